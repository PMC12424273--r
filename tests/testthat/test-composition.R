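test_that("bray_curtis matches the formula and vegdist", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 2)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "nv_degenerate_error")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), class = "nv_validation_error")

  set.seed(11)
  x <- matrix(runif(10 * 6), 10, 6, dimnames = list(paste0("T", 1:10), NULL))
  d_pkg <- outer(1:10, 1:10,
                 Vectorize(function(i, j) bray_curtis(x[i, ], x[j, ])))
  expect_equal(as.vector(as.dist(d_pkg)),
               as.vector(composition_dist(x)), tolerance = 1e-12)
})

test_that("two-way PERMANOVA partitions R2 and recovers separated groups", {
  des <- toy_design(3)  # 12 tanks, 3 per cell
  set.seed(12)
  comp <- matrix(runif(12 * 5), 12, 5, dimnames = list(des$tank_id, NULL))
  comp <- comp / rowSums(comp)
  d <- composition_dist(comp)
  tab <- permanova_two_way(d, des, n_perm = 99, seed = 1)
  expect_setequal(tab$term[1:3],
                  c("competition", "predation", "competition:predation"))
  r2 <- tab$R2[tab$term != "Total"]
  expect_equal(sum(r2), 1, tolerance = 1e-9)
  expect_equal(sum(tab$df[tab$term != "Total"]), 11)

  # two internally identical groups separated by a fixed offset: the group
  # factor absorbs essentially all variation
  base <- c(0.6, 0.3, 0.1, 0, 0)
  shift <- c(0, 0, 0.1, 0.5, 0.4)
  comp2 <- rbind(matrix(base, 4, 5, byrow = TRUE) +
                   matrix(rnorm(20, 0, 1e-6), 4, 5),
                 matrix(shift, 4, 5, byrow = TRUE) +
                   matrix(rnorm(20, 0, 1e-6), 4, 5))
  comp2 <- abs(comp2) / rowSums(abs(comp2))
  rownames(comp2) <- sprintf("T%02d", 1:8)
  des2 <- experiment_design(rownames(comp2), rep(c(0, 1), each = 4), 0)
  tab2 <- permanova_two_way(composition_dist(comp2), des2, n_perm = 999,
                            seed = 2)
  expect_gt(tab2$R2[tab2$term == "competition"], 0.999)
  # free relabelling: only permutations preserving the 4|4 split reach the
  # observed pseudo-F, so p is near 2 * 4!4!/8! ~ 0.029
  expect_lt(tab2$p[tab2$term == "competition"], 0.05)

  d0 <- dist(rep(0, 4))
  attr(d0, "Labels") <- toy_design(1)$tank_id
  expect_error(permanova_two_way(d0, toy_design(1)),
               class = "nv_degenerate_error")
})

test_that("PERMANOVA pseudo-F equals the classical F on univariate data", {
  set.seed(13)
  y <- rnorm(12)
  des <- toy_design(3)
  d <- dist(y)
  attr(d, "Labels") <- des$tank_id
  tab <- permanova_two_way(d, des, n_perm = 19, seed = 1)
  cls <- anova(lm(y ~ factor(des$competition) * factor(des$predation)))
  expect_equal(tab$F[1:3], cls$`F value`[1:3], tolerance = 1e-9)
  expect_equal(tab$SS[1:3], cls$`Sum Sq`[1:3], tolerance = 1e-9)
})

test_that("dispersion distances reduce to |x - group mean| in 1-D", {
  x <- c(1, 2, 6, 4, 9, 11)
  g <- rep(c("a", "b"), each = 3)
  d <- dist(x)
  attr(d, "Labels") <- paste0("T", 1:6)
  out <- dispersion_homogeneity(d, g, n_perm = 99, seed = 1)
  expected <- abs(x - ave(x, g))
  expect_equal(unname(out$distances), expected, tolerance = 1e-9)

  # identical points within a group -> zero dispersion for that group
  x2 <- c(5, 5, 5, 1, 2, 3)
  d2 <- dist(x2); attr(d2, "Labels") <- paste0("T", 1:6)
  out2 <- dispersion_homogeneity(d2, g, n_perm = 19, seed = 1)
  expect_equal(unname(out2$distances[1:3]), rep(0, 3), tolerance = 1e-9)

  # translation invariance: add a constant coordinate to every point
  out3 <- dispersion_homogeneity(dist(x + 100) |>
                                   (\(dd) { attr(dd, "Labels") <- paste0("T", 1:6); dd })(),
                                 g, n_perm = 19, seed = 1)
  expect_equal(unname(out3$distances), expected, tolerance = 1e-9)

  expect_error(dispersion_homogeneity(d, c("a", rep("b", 5))),
               class = "nv_validation_error")
})

test_that("SIMPER contributions sum to the mean between-group dissimilarity", {
  # single disjoint pair: each category contributes one half
  comp <- rbind(a = c(1, 0), b = c(0, 1))
  out <- simper_contributions(comp, factor(c("g1", "g2")), n_perm = 19,
                              seed = 1)
  expect_equal(sort(out$average), c(0.5, 0.5))
  expect_equal(attr(out, "overall"), 1)

  set.seed(14)
  for (rep in 1:10) {
    n <- 8
    comp <- matrix(runif(n * 6), n, 6, dimnames = list(paste0("T", 1:n), NULL))
    comp <- comp / rowSums(comp)
    g <- factor(rep(c("g1", "g2"), each = n / 2))
    out <- simper_contributions(comp, g, n_perm = 9)
    bc <- as.matrix(composition_dist(comp))
    expect_equal(sum(out$average), mean(bc[1:4, 5:8]), tolerance = 1e-10)
  }

  expect_error(simper_contributions(comp, factor(rep("g1", 8))),
               class = "nv_validation_error")
})

test_that("NMDS embeds planar configurations with near-zero stress,
           deterministically", {
  set.seed(15)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("T", 1:10)
  fit <- nmds_ordination(d, k = 2, n_starts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds_ordination(d, k = 2, n_starts = 10, seed = 3)
  expect_identical(fit$coordinates, fit2$coordinates)
  expect_error(nmds_ordination(dist(rnorm(3)), k = 2),
               class = "nv_validation_error")
})

test_that("fixed-configuration stress matches an isotonic-regression oracle
           and is scale invariant", {
  set.seed(16)
  for (rep in 1:10) {
    x <- matrix(rnorm(16), 8, 2)
    d <- dist(matrix(runif(24), 8, 3))
    s <- kruskal_stress(x, d)
    # oracle: stats::isoreg on configuration distances ordered by
    # dissimilarity (ties by configuration distance)
    conf <- as.vector(dist(x)); dv <- as.vector(d)
    ord <- order(dv, conf)
    fit <- stats::isoreg(conf[ord])$yf
    oracle <- sqrt(sum((conf[ord] - fit)^2) / sum(conf^2))
    expect_equal(s, oracle, tolerance = 1e-12)
    expect_equal(kruskal_stress(x, d * 3), s, tolerance = 1e-12)
  }
})
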