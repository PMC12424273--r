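#' Shannon entropy of a proportion vector
#'
#' @param p Non-negative proportions summing to 1 (tolerance 1e-9). Zero
#'   entries contribute nothing (0 log 0 = 0).
#' @return Entropy in nats (natural log).
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # log(2)
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0))
    nv_stop("proportions must be non-negative", "nv_validation_error")
  if (abs(sum(p) - 1) > 1e-9)
    nv_stop("proportions must sum to 1", "nv_validation_error")
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

# x * log(x) with the 0 log 0 = 0 convention, elementwise on matrices.
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Resource-use proportion arrays of a population
#'
#' Computes from an individuals x categories count matrix the four
#' proportion arrays underlying the Shannon niche partition:
#' \describe{
#'   \item{p_ij}{proportion of individual i's use made of category j
#'     (rows sum to 1);}
#'   \item{p_i}{proportion of the population's total use contributed by
#'     individual i (sums to 1);}
#'   \item{q}{proportion of population use made of category j, computed from
#'     summed counts, so \eqn{q_j = \sum_i p_{i\cdot} p_{ij}};}
#'   \item{gamma_ij}{proportion of the population's use of category j
#'     accounted for by individual i (columns sum to 1).}
#' }
#'
#' @param m Count matrix with all row sums and column sums positive. Use
#'   [drop_empty_individuals()] to clear zero rows/columns first.
#' @return List with elements `p_ij`, `p_i`, `q`, `gamma_ij`.
#' @export
niche_proportions <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 1L)
    nv_stop("matrix has no individuals", "nv_validation_error")
  r <- rowSums(m); cs <- colSums(m)
  if (any(r == 0) || any(cs == 0))
    nv_stop(paste("matrix has all-zero rows or columns;",
                  "apply drop_empty_individuals() before decomposing"),
            "nv_validation_error")
  total <- sum(m)
  list(p_ij = m / r,
       p_i = r / total,
       q = cs / total,
       gamma_ij = sweep(m, 2L, cs, "/"))
}

#' Shannon partition of total niche width
#'
#' Partitions the Shannon entropy of a population's pooled resource use
#' (total niche width, TNW) into the within-individual component (WIC, the
#' use-weighted mean entropy of individual resource distributions) and the
#' between-individual component (BIC = TNW - WIC, the mutual information
#' between individual identity and resource category). The individual
#' specialisation index is the complement 1 - WIC/TNW: 0 for identical
#' generalists, 1 for individuals using disjoint resource sets.
#'
#' All entropies use natural logarithms (nats). Individual weights
#' \eqn{p_{i\cdot}} are count-proportional: individuals contributing more
#' items to the population total carry more weight in WIC.
#'
#' @param m Count matrix (individuals x categories) with positive row and
#'   column sums; at least 2 categories are required for a defined index.
#' @return Object of class `niche_components`: list with `WIC`, `BIC`,
#'   `TNW` (nats), `is_index`, `n_individuals`, `n_categories`, `n_items`
#'   and the matrix `tank_id`/`niche_kind` metadata when present.
#' @examples
#' # two perfect specialists on disjoint resources
#' niche_decompose(matrix(c(2, 0, 0, 2), 2, 2))
#' @export
niche_decompose <- function(m) {
  pr <- niche_proportions(m)
  if (length(pr$q) < 2L || shannon_entropy(pr$q) == 0)
    nv_stop("population uses a single resource category: TNW = 0 and the
 specialisation index is undefined", "nv_degenerate_error")
  TNW <- -sum(xlogx(pr$q))
  WIC <- sum(pr$p_i * -rowSums(xlogx(pr$p_ij)))
  # mutual-information form: H(individual) - sum_j q_j * H(gamma_.j)
  BIC <- -sum(xlogx(pr$p_i)) - sum(pr$q * -colSums(xlogx(pr$gamma_ij)))
  structure(list(WIC = WIC, BIC = BIC, TNW = TNW,
                 is_index = 1 - WIC / TNW,
                 n_individuals = nrow(m), n_categories = ncol(m),
                 n_items = sum(m),
                 tank_id = attr(m, "tank_id") %||% NA_character_,
                 niche_kind = attr(m, "niche_kind") %||% NA_character_),
            class = "niche_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.niche_components <- function(x, ...) {
  cat(sprintf(
    "niche components (%s, tank '%s'): %d individuals, %d categories\n",
    x$niche_kind, x$tank_id, x$n_individuals, x$n_categories))
  cat(sprintf("  TNW = %.4f  WIC = %.4f  BIC = %.4f  (nats)\n",
              x$TNW, x$WIC, x$BIC))
  cat(sprintf("  1 - WIC/TNW = %.4f\n", x$is_index))
  invisible(x)
}

#' Individual specialisation index 1 - WIC/TNW
#'
#' @param x A `niche_components` object ([niche_decompose()]) or a count
#'   matrix, which is decomposed first.
#' @return The index in \[0, 1\].
#' @export
is_index <- function(x) {
  if (!inherits(x, "niche_components")) x <- niche_decompose(x)
  if (x$TNW <= 0)
    nv_stop("TNW = 0: specialisation index undefined", "nv_degenerate_error")
  x$is_index
}

# Lean numeric core used in simulation-heavy paths (no validation, no class).
# Uses sum(n log n) identities: WIC = sum_i (r_i log r_i - S_i) / T,
# TNW = log T - sum_j c_j log c_j / T.
.is_index_counts <- function(m) {
  total <- sum(m)
  r <- rowSums(m)
  cs <- colSums(m)
  S <- rowSums(xlogx(unclass(m)))
  WIC <- sum(xlogx(r) - S) / total
  TNW <- log(total) - sum(xlogx(cs)) / total
  if (TNW <= 0) return(NA_real_)
  1 - WIC / TNW
}
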