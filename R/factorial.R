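#' Fit a 2x2 factorial linear model to per-tank responses
#'
#' Ordinary least squares of a scalar per-tank response (a niche component
#' or specialisation index) on competition, predation and their interaction,
#' under sum-to-zero factor coding (required for meaningful Type III sums of
#' squares). Both Type III and Type II SS tables are computed at fit time.
#'
#' @param response Named numeric vector of per-tank values (names =
#'   tank_id). Tanks missing from the design are an error; `NA` values are
#'   dropped.
#' @param design Design table from [experiment_design()].
#' @param transform `"none"` or `"log"` (natural log; requires strictly
#'   positive values and errors naming the first offending tank).
#' @param response_name Label used in printed output.
#' @return Object of class `factorial_fit`: list with the `lm` fit, the
#'   model data, `ss3`/`ss2` (car Type III / Type II ANOVA tables), cell
#'   means and counts, `mse`, `df_residual`, `transform`.
#' @export
fit_2x2 <- function(response, design, transform = c("none", "log"),
                    response_name = deparse(substitute(response))) {
  transform <- match.arg(transform)
  if (is.null(names(response)))
    nv_stop("response must be named by tank_id", "nv_validation_error")
  response <- response[!is.na(response)]
  missing <- setdiff(names(response), design$tank_id)
  if (length(missing) > 0L)
    nv_stop(paste0("tanks absent from design: ", paste(missing, collapse = ", ")),
            "nv_validation_error")
  des <- design[match(names(response), design$tank_id), , drop = FALSE]
  if (transform == "log") {
    if (any(response <= 0))
      nv_stop(paste0("log transform needs strictly positive values; tank '",
                     names(response)[which(response <= 0)[1L]], "' is not"),
              "nv_validation_error")
    response <- log(response)
  }
  dat <- data.frame(y = as.numeric(response),
                    competition = factor(des$competition, levels = 0:1),
                    predation = factor(des$predation, levels = 0:1),
                    treatment = des$treatment,
                    tank_id = des$tank_id)
  cells <- table(dat$competition, dat$predation)
  if (any(cells == 0L))
    nv_stop("empty design cell: interaction model not estimable",
            "nv_estimability_error")
  fit <- stats::lm(y ~ competition * predation, data = dat,
                   contrasts = list(competition = "contr.sum",
                                    predation = "contr.sum"))
  if (sum(resid(fit)^2) > 1e-10 * max(1, sum(dat$y^2))) {
    ss3 <- car::Anova(fit, type = 3)
    ss2 <- car::Anova(fit, type = 2)
  } else {
    # perfect fit: car::Anova refuses a zero residual SS, but the SS
    # partition is still well defined; compute it by direct projection
    ss3 <- projection_ss(fit, type = 3)
    ss2 <- projection_ss(fit, type = 2)
  }
  cm <- tapply(dat$y, dat$treatment, mean)
  cn <- tapply(dat$y, dat$treatment, length)
  dfr <- fit$df.residual
  structure(list(lm = fit, data = dat, ss3 = ss3, ss2 = ss2,
                 cell_means = cm, cell_n = cn,
                 mse = if (dfr > 0) sum(resid(fit)^2) / dfr else NA_real_,
                 df_residual = dfr, transform = transform,
                 response_name = response_name),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("2x2 factorial fit of '%s'%s on %d tanks\n", x$response_name,
              if (x$transform == "log") " (log scale)" else "",
              nrow(x$data)))
  print(anova_report(x))
  invisible(x)
}

# Type II / III sums of squares by comparing residual SS of column-subset
# projections of the sum-coded model matrix (same partition car::Anova
# computes; used when the fit is perfect and car refuses to proceed).
projection_ss <- function(fit, type) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  asgn <- attr(X, "assign")        # 0 intercept, 1 comp, 2 pred, 3 interaction
  rss <- function(keep) {
    q <- qr(X[, keep, drop = FALSE])
    sum(qr.resid(q, y)^2)
  }
  full <- rss(seq_len(ncol(X)))
  ss <- if (type == 3) {
    c(competition = rss(asgn != 1) - full,
      predation = rss(asgn != 2) - full,
      `competition:predation` = rss(asgn != 3) - full)
  } else {
    c(competition = rss(asgn %in% c(0, 2)) - rss(asgn %in% 0:2),
      predation = rss(asgn %in% c(0, 1)) - rss(asgn %in% 0:2),
      `competition:predation` = rss(asgn %in% 0:2) - full)
  }
  dfr <- fit$df.residual
  mse <- if (dfr > 0) full / dfr else NA_real_
  Fv <- if (!is.na(mse) && mse > 0) ss / mse else rep(NA_real_, 3)
  out <- data.frame(
    `Sum Sq` = c(ss, Residuals = full),
    Df = c(1, 1, 1, dfr),
    `F value` = c(Fv, NA),
    `Pr(>F)` = c(stats::pf(Fv, 1, dfr, lower.tail = FALSE), NA),
    check.names = FALSE)
  rownames(out) <- c(names(ss), "Residuals")
  out
}

# Extract (SS, df, F, p) for a term from a car::Anova table.
term_row <- function(tab, term) {
  i <- match(term, rownames(tab))
  list(SS = tab[i, "Sum Sq"], df = tab[i, "Df"],
       F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
}

#' Per-term ANOVA table with the interaction-gated SS choice
#'
#' Implements the standard decision flow for unbalanced factorials: the
#' interaction is always judged from Type III sums of squares; if it is
#' non-significant at `alpha`, main effects are reported from Type II SS
#' (which respect marginality and have more power absent an interaction),
#' otherwise every term is reported from Type III. Partial eta squared
#' (\eqn{SS_{term} / (SS_{term} + SS_{resid})}) is computed from the same SS
#' used for each term's F test.
#'
#' @param fit A `factorial_fit`.
#' @param alpha Significance gate for the interaction (default 0.05).
#' @return data.frame (`term`, `ss_type`, `df`, `SS`, `F`, `p`,
#'   `partial_eta_sq`) with rows competition, predation,
#'   competition:predation, residual.
#' @export
anova_report <- function(fit, alpha = 0.05) {
  if (fit$df_residual == 0L)
    nv_stop("zero residual degrees of freedom: F tests undefined",
            "nv_degenerate_error")
  ss_res <- sum(resid(fit$lm)^2)
  int3 <- term_row(fit$ss3, "competition:predation")
  use_type2 <- is.na(int3$p) || int3$p >= alpha
  main_tab <- if (use_type2) fit$ss2 else fit$ss3
  main_type <- if (use_type2) "II" else "III"
  rows <- list(
    c(list(term = "competition", ss_type = main_type),
      term_row(main_tab, "competition")),
    c(list(term = "predation", ss_type = main_type),
      term_row(main_tab, "predation")),
    c(list(term = "competition:predation", ss_type = "III"), int3)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(term = r$term, ss_type = r$ss_type, df = r$df, SS = r$SS,
               F = r$F, p = r$p,
               partial_eta_sq = r$SS / (r$SS + ss_res),
               stringsAsFactors = FALSE)))
  out <- rbind(out, data.frame(term = "residual", ss_type = "",
                               df = fit$df_residual, SS = ss_res,
                               F = NA_real_, p = NA_real_,
                               partial_eta_sq = NA_real_))
  rownames(out) <- NULL
  out
}

#' Partial eta squared for a model term
#'
#' @param fit A `factorial_fit`.
#' @param term One of `"competition"`, `"predation"`,
#'   `"competition:predation"`.
#' @param alpha Interaction gate passed through to [anova_report()], which
#'   determines whether main-effect SS are Type II or Type III.
#' @return \eqn{SS_{term} / (SS_{term} + SS_{resid})} in \[0, 1\].
#' @export
partial_eta_squared <- function(fit, term, alpha = 0.05) {
  tab <- anova_report(fit, alpha = alpha)
  i <- match(term, tab$term)
  if (is.na(i) || term == "residual")
    nv_stop(paste0("unknown model term '", term, "'"), "nv_validation_error")
  denom <- tab$SS[i] + tab$SS[tab$term == "residual"]
  if (denom == 0)
    nv_stop("zero total SS: partial eta squared undefined",
            "nv_degenerate_error")
  tab$SS[i] / denom
}

#' Tukey HSD pairwise comparisons among the four treatment cells
#'
#' Treats the 2x2 design as a 4-level cell-means model and compares all six
#' treatment pairs, with studentized-range adjusted p-values
#' (Tukey-Kramer standard errors under unbalanced cells) and a compact
#' letter display at `alpha`.
#'
#' @param fit A `factorial_fit`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `pairs` (data.frame: contrast, estimate, SE, q,
#'   p_adj) and `letters` (named character vector per treatment; treatments
#'   sharing no letter differ significantly).
#' @export
tukey_pairwise <- function(fit, alpha = 0.05) {
  if (is.na(fit$mse) || fit$mse <= 0)
    nv_stop("zero residual variance: post-hoc comparisons undefined",
            "nv_degenerate_error")
  means <- fit$cell_means
  n <- fit$cell_n
  present <- !is.na(means)
  means <- means[present]; n <- n[present]
  k <- length(means)
  dfr <- fit$df_residual
  combs <- utils::combn(names(means), 2L)
  est <- se <- q <- p <- numeric(ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    a <- combs[1L, c_i]; b <- combs[2L, c_i]
    est[c_i] <- means[a] - means[b]
    se[c_i] <- sqrt(fit$mse * (1 / n[a] + 1 / n[b]))
    q[c_i] <- abs(est[c_i]) / (se[c_i] / sqrt(2))  # Tukey-Kramer
    p[c_i] <- stats::ptukey(q[c_i], nmeans = k, df = dfr, lower.tail = FALSE)
  }
  pairs <- data.frame(contrast = paste(combs[1L, ], "-", combs[2L, ]),
                      estimate = est, SE = se, q = q, p_adj = p,
                      stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (c_i in seq_len(ncol(combs)))
    sig[combs[1L, c_i], combs[2L, c_i]] <-
      sig[combs[2L, c_i], combs[1L, c_i]] <- p[c_i] < alpha
  list(pairs = pairs, letters = cld_letters(sig))
}

# Compact letter display by insert-and-absorb: maintain a set of
# "homogeneous groups" (logical columns); split any group containing a
# significantly different pair, then drop groups contained in another.
cld_letters <- function(sig) {
  labs <- rownames(sig)
  groups <- list(rep(TRUE, length(labs)))
  idx <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    new_groups <- list()
    for (g in groups) {
      if (g[i] && g[j]) {
        g1 <- g; g1[i] <- FALSE
        g2 <- g; g2[j] <- FALSE
        new_groups <- c(new_groups, list(g1, g2))
      } else new_groups <- c(new_groups, list(g))
    }
    # absorb groups that are subsets of another
    keep <- rep(TRUE, length(new_groups))
    for (a in seq_along(new_groups)) for (b in seq_along(new_groups)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_groups[[a]] <= new_groups[[b]]) &&
          any(new_groups[[a]] < new_groups[[b]]))
        keep[a] <- FALSE
    }
    dup <- duplicated(new_groups)
    groups <- new_groups[keep & !dup]
  }
  out <- stats::setNames(rep("", length(labs)), labs)
  for (g_i in seq_along(groups))
    out[groups[[g_i]]] <- paste0(out[groups[[g_i]]], letters[g_i])
  out
}

#' Numeric residual diagnostics for a factorial fit
#'
#' Replaces graphical residual inspection with advisory numeric summaries:
#' residual skewness and excess kurtosis, and the max/min ratio of
#' within-cell residual variances. Flags are raised when |skewness| > 1 or
#' the variance ratio exceeds 4; constant residuals raise a degenerate flag.
#'
#' @param fit A `factorial_fit`.
#' @return List with `skewness`, `kurtosis_excess`, `variance_ratio`,
#'   `flags` (character vector, possibly empty).
#' @export
residual_diagnostics <- function(fit) {
  r <- resid(fit$lm)
  m2 <- mean((r - mean(r))^2)
  flags <- character(0)
  if (m2 < 1e-24) {
    return(list(skewness = NA_real_, kurtosis_excess = NA_real_,
                variance_ratio = NA_real_, flags = "degenerate_residuals"))
  }
  skew <- mean((r - mean(r))^3) / m2^1.5
  kurt <- mean((r - mean(r))^4) / m2^2 - 3
  cell_var <- tapply(r, fit$data$treatment, stats::var)
  cell_var <- cell_var[!is.na(cell_var) & cell_var > 0]
  vr <- if (length(cell_var) >= 2L) max(cell_var) / min(cell_var) else NA_real_
  if (abs(skew) > 1) flags <- c(flags, "skewed_residuals")
  if (!is.na(vr) && vr > 4) flags <- c(flags, "heteroscedastic_cells")
  list(skewness = skew, kurtosis_excess = kurt, variance_ratio = vr,
       flags = flags)
}
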