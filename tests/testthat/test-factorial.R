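test_that("interaction SS matches the projection oracle on a clean design", {
  # balanced 2 obs/cell, cell means (1,1,1,3), zero residual noise:
  # SS_A = SS_B = SS_AB = 2 under sum-to-zero coding
  des <- toy_design(2)
  means <- c(1, 1, 1, 3)[1 + des$predation + 2 * des$competition]
  y <- setNames(means, des$tank_id)
  fit <- fit_2x2(y, des)
  expect_equal(fit$ss3["competition", "Sum Sq"], 2, tolerance = 1e-9)
  expect_equal(fit$ss3["predation", "Sum Sq"], 2, tolerance = 1e-9)
  expect_equal(fit$ss3["competition:predation", "Sum Sq"], 2,
               tolerance = 1e-9)
  expect_equal(sum(resid(fit$lm)^2), 0, tolerance = 1e-18)
})

test_that("Type II and Type III SS agree on balanced designs", {
  set.seed(21)
  for (rep in 1:10) {
    des <- toy_design(3)
    y <- setNames(rnorm(nrow(des)), des$tank_id)
    fit <- fit_2x2(y, des)
    for (term in c("competition", "predation", "competition:predation"))
      expect_equal(fit$ss2[term, "Sum Sq"], fit$ss3[term, "Sum Sq"],
                   tolerance = 1e-9)
  }
})

test_that("anova_report gates main-effect SS type on the interaction", {
  set.seed(22)
  des <- toy_design(4)
  # unbalanced: drop two tanks so II and III genuinely differ
  des <- des[-c(1, 5), ]

  # additive data -> non-significant interaction -> Type II mains
  y_add <- setNames(2 * des$competition + rnorm(nrow(des), 0, 0.5),
                    des$tank_id)
  rep_add <- anova_report(fit_2x2(y_add, des))
  expect_equal(rep_add$ss_type[rep_add$term == "competition"], "II")
  expect_equal(rep_add$ss_type[rep_add$term == "competition:predation"], "III")

  # strong crossover interaction -> everything Type III
  y_int <- setNames(3 * des$competition * des$predation +
                      rnorm(nrow(des), 0, 0.3), des$tank_id)
  rep_int <- anova_report(fit_2x2(y_int, des))
  expect_lt(rep_int$p[rep_int$term == "competition:predation"], 0.05)
  expect_equal(rep_int$ss_type[rep_int$term == "competition"], "III")
})

test_that("F statistics are invariant to affine rescaling of the response", {
  set.seed(23)
  des <- toy_design(3)[-1, ]
  y <- setNames(rnorm(11), des$tank_id)
  f1 <- anova_report(fit_2x2(y, des))
  f2 <- anova_report(fit_2x2(7 * y + 3, des))
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})

test_that("partial eta squared follows its SS definition", {
  set.seed(24)
  des <- toy_design(3)
  y <- setNames(des$competition + rnorm(12, 0, 0.7), des$tank_id)
  fit <- fit_2x2(y, des)
  tab <- anova_report(fit)
  ss_res <- tab$SS[tab$term == "residual"]
  for (term in c("competition", "predation")) {
    ss <- tab$SS[tab$term == term]
    expect_equal(partial_eta_squared(fit, term), ss / (ss + ss_res))
  }
  eta <- partial_eta_squared(fit, "competition")
  expect_gte(eta, 0); expect_lte(eta, 1)
  expect_error(partial_eta_squared(fit, "nonsense"),
               class = "nv_validation_error")
})

test_that("Tukey HSD adjusted p matches the base TukeyHSD oracle", {
  set.seed(25)
  des <- toy_design(5)
  y <- setNames(c(0, 0.8, 1.5, 0.2)[1 + des$predation + 2 * des$competition] +
                  rnorm(20, 0, 0.6), des$tank_id)
  fit <- fit_2x2(y, des)
  out <- tukey_pairwise(fit)
  oracle <- TukeyHSD(aov(y ~ treatment,
                         data = data.frame(y = y, treatment = des$treatment)))
  otab <- oracle$treatment
  # match contrasts irrespective of orientation
  for (i in seq_len(nrow(out$pairs))) {
    ab <- strsplit(out$pairs$contrast[i], " - ", fixed = TRUE)[[1]]
    key <- paste(ab[2], ab[1], sep = "-")
    if (!key %in% rownames(otab)) key <- paste(ab[1], ab[2], sep = "-")
    expect_equal(out$pairs$p_adj[i], otab[key, "p adj"], tolerance = 1e-6)
  }
  # multiplicity monotonicity: adjusted p >= the unadjusted t p computed
  # from the same estimate, SE and residual df
  raw <- 2 * pt(-abs(out$pairs$estimate) / out$pairs$SE, fit$df_residual)
  expect_true(all(out$pairs$p_adj + 1e-12 >= raw))
})

test_that("letter display separates means consistently with the tests", {
  set.seed(26)
  des <- toy_design(5)
  # all means equal: one shared letter
  y0 <- setNames(rnorm(20), des$tank_id)
  l0 <- tukey_pairwise(fit_2x2(y0, des))$letters
  expect_true(all(l0 == l0[1]))

  # one extreme cell: its letter set disjoint from the rest
  y1 <- setNames(10 * (des$treatment == "competition") + rnorm(20, 0, 0.3),
                 des$tank_id)
  out1 <- tukey_pairwise(fit_2x2(y1, des))
  lets <- strsplit(out1$letters, "")
  others <- setdiff(names(out1$letters), "competition")
  for (o in others)
    expect_length(intersect(lets[["competition"]], lets[[o]]), 0)
})

test_that("residual diagnostics flag skew and degeneracy, not clean fits", {
  des <- toy_design(10)
  set.seed(27)
  clean <- residual_diagnostics(
    fit_2x2(setNames(rnorm(40), des$tank_id), des))
  expect_length(clean$flags, 0)

  set.seed(27)
  skewed <- residual_diagnostics(
    fit_2x2(setNames(exp(rnorm(40, 0, 1.2)), des$tank_id), des))
  expect_true("skewed_residuals" %in% skewed$flags)

  des <- toy_design(6)

  const <- residual_diagnostics(
    fit_2x2(setNames(rep(c(1, 2, 3, 4), each = 6), des$tank_id), des))
  expect_equal(const$flags, "degenerate_residuals")
})

test_that("log transform and estimability guards work", {
  des <- toy_design(2)
  y <- setNames(seq(0.5, 4, length.out = 8), des$tank_id)
  fit <- fit_2x2(y, des, transform = "log")
  expect_equal(unname(fit$data$y), log(unname(y)))
  y_bad <- y; y_bad[3] <- -1
  expect_error(fit_2x2(y_bad, des, transform = "log"), "T03")

  des_missing <- des[des$treatment != "control", ]
  expect_error(fit_2x2(y[des_missing$tank_id], des_missing),
               class = "nv_estimability_error")
})
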