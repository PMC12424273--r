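#' Bray-Curtis dissimilarity between two composition vectors
#'
#' \eqn{\sum_j |x_j - y_j| / \sum_j (x_j + y_j)}; 0 for identical vectors,
#' 1 for vectors with disjoint support.
#'
#' @param x,y Equal-length non-negative vectors (not both all-zero).
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    nv_stop("vectors must have equal length", "nv_validation_error")
  if (any(x < 0) || any(y < 0))
    nv_stop("Bray-Curtis requires non-negative entries", "nv_validation_error")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    nv_stop("Bray-Curtis undefined for two all-zero vectors",
            "nv_degenerate_error")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis distance matrix among tank compositions
#'
#' @param comp Matrix of compositions, one row per tank (rows named by
#'   tank_id), e.g. stacked [tank_mean_composition()] vectors.
#' @return A `dist` object with tank labels.
#' @export
composition_dist <- function(comp) {
  comp <- as.matrix(comp)
  if (is.null(rownames(comp)))
    nv_stop("composition matrix must have tank ids as rownames",
            "nv_validation_error")
  vegan::vegdist(comp, method = "bray")
}

# Align a design table to the labels of a dist object; errors on mismatch.
align_design <- function(d, design) {
  labs <- attr(d, "Labels")
  if (is.null(labs))
    nv_stop("distance matrix has no labels", "nv_validation_error")
  missing <- setdiff(labs, design$tank_id)
  if (length(missing) > 0L)
    nv_stop(paste0("tanks absent from design: ",
                   paste(missing, collapse = ", ")), "nv_validation_error")
  design[match(labs, design$tank_id), , drop = FALSE]
}

#' Two-way PERMANOVA on a dissimilarity matrix
#'
#' Partitions squared Bray-Curtis dissimilarities among the competition and
#' predation factors and their interaction, entering terms sequentially in
#' that order, with significance by free permutation of tank labels. A thin
#' wrapper around [vegan::adonis2()] that returns a tidy per-term table.
#'
#' @param d `dist` of tank-level dissimilarities with tank labels.
#' @param design Design table from [experiment_design()] covering all tanks
#'   in `d`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @param permutations Optional explicit permutation matrix (rows =
#'   permutations of the tank indices); overrides `n_perm`. Useful for
#'   exhaustive enumeration on small designs.
#' @param by Term assessment mode passed to [vegan::adonis2()]:
#'   `"terms"` (sequential, default) or `"margin"`.
#' @return A data.frame (`term`, `df`, `SS`, `R2`, `F`, `p`) with one row
#'   per model term plus the residual and total rows.
#' @export
permanova_two_way <- function(d, design, n_perm = 999, seed = NULL,
                              permutations = NULL, by = "terms") {
  des <- align_design(d, design)
  if (stats::var(as.vector(d)) == 0)
    nv_stop("constant distance matrix: PERMANOVA is degenerate",
            "nv_degenerate_error")
  dat <- data.frame(competition = factor(des$competition),
                    predation = factor(des$predation))
  if (!is.null(seed)) set.seed(seed)
  perm <- permutations %||% n_perm
  form <- if (nlevels(dat$competition) > 1L && nlevels(dat$predation) > 1L)
    d ~ competition * predation
  else if (nlevels(dat$competition) > 1L) d ~ competition else d ~ predation
  fit <- vegan::adonis2(form, data = dat, permutations = perm, by = by)
  data.frame(term = rownames(fit), df = fit$Df, SS = fit$SumOfSqs,
             R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether groups differ in their spread around group centroids in the
#' principal-coordinate embedding of a dissimilarity matrix (the
#' betadisper/PERMDISP approach), with a permutation F-test.
#'
#' @param d `dist` object.
#' @param groups Factor of group membership, aligned to the labels of `d`
#'   (or a design table, in which case the treatment column is used).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return List with `distances` (named per-sample distance to its group
#'   centroid), `F`, `p` and the underlying `betadisper` fit.
#' @export
dispersion_homogeneity <- function(d, groups, n_perm = 999, seed = NULL) {
  if (is.data.frame(groups)) {
    des <- align_design(d, groups)
    groups <- des$treatment
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    nv_stop("need at least two groups", "nv_validation_error")
  if (any(table(groups) < 2L))
    nv_stop("every group needs at least two members", "nv_validation_error")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(distances = stats::setNames(bd$distances, attr(d, "Labels")),
       F = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L], fit = bd)
}

#' SIMPER: per-category contributions to between-group dissimilarity
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' additive per-category contributions (the contribution of category j is
#' the mean over between-group sample pairs of
#' \eqn{|x_{aj} - x_{bj}| / \sum_k (x_{ak} + x_{bk})}), with permutation
#' significance for each category. Wraps [vegan::simper()].
#'
#' @param comp Composition matrix (rows = tanks, named).
#' @param groups Two-level factor aligned to the rows of `comp`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return data.frame (`category`, `average`, `mean_a`, `mean_b`, `p`)
#'   sorted by decreasing contribution; attribute `overall` holds the mean
#'   between-group dissimilarity (equal to `sum(average)`).
#' @export
simper_contributions <- function(comp, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) != 2L)
    nv_stop("SIMPER contrast needs exactly two non-empty groups",
            "nv_validation_error")
  comp <- as.matrix(comp)
  if (is.null(colnames(comp)))
    colnames(comp) <- paste0("c", seq_len(ncol(comp)))
  if (any(table(groups) < 2L)) {
    # a single-member group leaves nothing to permute (and trips vegan);
    # report the contribution decomposition with p undefined
    avg <- simper_average(comp, groups)
    out <- data.frame(category = colnames(comp), average = avg,
                      mean_a = colMeans(comp[groups == levels(groups)[1L], ,
                                             drop = FALSE]),
                      mean_b = colMeans(comp[groups == levels(groups)[2L], ,
                                             drop = FALSE]),
                      p = NA_real_, stringsAsFactors = FALSE)
  } else {
  if (!is.null(seed)) set.seed(seed)
  s <- vegan::simper(comp, groups, permutations = n_perm)
  sm <- s[[1L]]
  out <- data.frame(category = sm$species, average = sm$average,
                    mean_a = sm$ava, mean_b = sm$avb, p = sm$p,
                    stringsAsFactors = FALSE)
  }
  out <- out[order(-out$average), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overall") <- sum(out$average)
  attr(out, "contrast") <- paste(levels(groups), collapse = "_")
  out
}

#' Non-metric multidimensional scaling of tank compositions
#'
#' Best-of-several-starts NMDS minimising Kruskal stress-1, via
#' [vegan::metaMDS()] on a precomputed dissimilarity matrix (no internal
#' transformation or autodetection).
#'
#' @param d `dist` object (n points, n >= k + 2).
#' @param k Ordination dimension (default 2).
#' @param n_starts Number of random starts (default 20).
#' @param seed Optional seed.
#' @return List with `coordinates` (n x k matrix), `stress` (Kruskal
#'   stress-1), `converged`, `n_starts`, `seed`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = NULL) {
  n <- attr(d, "Size")
  if (n < k + 2)
    nv_stop("too few points for the requested dimension", "nv_validation_error")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  list(coordinates = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
       n_starts = n_starts, seed = seed %||% NA_integer_, fit = fit)
}

#' Kruskal stress-1 of a fixed configuration
#'
#' Evaluates how faithfully a given low-dimensional configuration represents
#' a dissimilarity matrix: configuration distances are regressed
#' monotonically on the dissimilarities (pool-adjacent-violators, ties
#' broken by configuration distance) and stress-1 is
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} over the fitted configuration
#' distances d.
#'
#' @param coords n x k coordinate matrix.
#' @param d `dist` of the original dissimilarities (same n).
#' @return Stress-1 in \[0, 1\].
#' @export
kruskal_stress <- function(coords, d) {
  dvec <- as.vector(d)
  conf <- as.vector(stats::dist(coords))
  if (length(dvec) != length(conf))
    nv_stop("configuration and dissimilarity sizes differ",
            "nv_validation_error")
  ord <- order(dvec, conf)
  fit <- pava(conf[ord])
  sqrt(sum((conf[ord] - fit)^2) / sum(conf^2))
}

# Average SIMPER contribution of each category: mean over between-group
# sample pairs (a, b) of |x_aj - x_bj| / sum_k(x_ak + x_bk).
simper_average <- function(comp, groups) {
  ia <- which(groups == levels(groups)[1L])
  ib <- which(groups == levels(groups)[2L])
  acc <- numeric(ncol(comp))
  for (a in ia) for (b in ib)
    acc <- acc + abs(comp[a, ] - comp[b, ]) / sum(comp[a, ] + comp[b, ])
  acc / (length(ia) * length(ib))
}

# Pool-adjacent-violators: least-squares monotone non-decreasing fit with
# unit weights.
pava <- function(y) {
  n <- length(y)
  val <- y
  w <- rep(1, n)
  j <- 0L
  for (i in seq_len(n)) {
    j <- j + 1L
    val[j] <- y[i]; w[j] <- 1
    while (j > 1L && val[j - 1L] > val[j]) {
      val[j - 1L] <- (w[j - 1L] * val[j - 1L] + w[j] * val[j]) / (w[j - 1L] + w[j])
      w[j - 1L] <- w[j - 1L] + w[j]
      j <- j - 1L
    }
  }
  rep.int(val[seq_len(j)], w[seq_len(j)])
}
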