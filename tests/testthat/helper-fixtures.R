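# Shared fixtures: random matrices, a from-first-principles decomposition
# oracle, and small CSV writers.

# Random non-degenerate count matrix (no all-zero rows or columns).
random_count_matrix <- function(n_ind, n_cat, max_count = 8) {
  repeat {
    m <- matrix(sample(0:max_count, n_ind * n_cat, replace = TRUE,
                       prob = c(4, rep(1, max_count))),
                n_ind, n_cat,
                dimnames = list(sprintf("i%d", seq_len(n_ind)),
                                sprintf("c%d", seq_len(n_cat))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Brute-force Shannon niche partition written as explicit loops over the
# four proportion definitions; deliberately naive and independent of the
# package's vectorised implementation.
oracle_decompose <- function(m) {
  total <- sum(m)
  n <- nrow(m); k <- ncol(m)
  r <- rowSums(m); cs <- colSums(m)
  p_i <- r / total
  q <- cs / total
  WIC <- 0
  for (i in seq_len(n)) {
    H_i <- 0
    for (j in seq_len(k)) {
      p <- m[i, j] / r[i]
      if (p > 0) H_i <- H_i - p * log(p)
    }
    WIC <- WIC + p_i[i] * H_i
  }
  TNW <- 0
  for (j in seq_len(k)) if (q[j] > 0) TNW <- TNW - q[j] * log(q[j])
  H_ind <- 0
  for (i in seq_len(n)) if (p_i[i] > 0) H_ind <- H_ind - p_i[i] * log(p_i[i])
  cond <- 0
  for (j in seq_len(k)) {
    H_g <- 0
    for (i in seq_len(n)) {
      g <- m[i, j] / cs[j]
      if (g > 0) H_g <- H_g - g * log(g)
    }
    cond <- cond + q[j] * H_g
  }
  list(WIC = unname(WIC), BIC = unname(H_ind - cond), TNW = unname(TNW))
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

toy_records <- function() {
  data.frame(
    tank_id = "T1",
    individual_id = c("A", "A", "A", "B"),
    session = c("s1", "s2", "s2", "s1"),
    category = c("chironomid", "chironomid", "ostracod", "ostracod"),
    count = c(2L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
}

# Balanced 2x2 design with n tanks per cell.
toy_design <- function(n_per_cell = 2) {
  cells <- expand.grid(competition = 0:1, predation = 0:1)
  experiment_design(
    sprintf("T%02d", seq_len(4 * n_per_cell)),
    rep(cells$competition, each = n_per_cell),
    rep(cells$predation, each = n_per_cell))
}
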