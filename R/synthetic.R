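#' Default population diet composition (14 prey taxa)
#'
#' Average stomach-content proportions of the focal benthic fish across all
#' individuals and treatments in the mesocosm system this generator
#' emulates: a cladoceran/chironomid-dominated assemblage with rarer
#' copepods, ostracods, gastropods and insects. Used as the baseline
#' multinomial composition q of the synthetic generator.
#'
#' @return Named numeric vector of 14 proportions summing to 1.
#' @export
default_diet_composition <- function() {
  q <- c("Acari" = 0.3, "Ceriodaphnia spp." = 26.8, "Chydorus spp." = 33.6,
         "Cyclopoida" = 4.4, "Chironomidae larvae" = 24.1,
         "Chironomidae pupae" = 0.1, "Ceratopogonidae larvae" = 0.1,
         "Tanypodinae" = 0.4, "Potamopyrgus sp." = 1.0, "Physidae" = 0.1,
         "Planorbidae" = 0.4, "Ostracoda" = 8.5, "Hemiptera" = 0.0,
         "Odonata" = 0.2)
  q / sum(q)
}

#' Default microhabitat composition (8 categories)
#'
#' Baseline scan-observation proportions over the mesocosm microhabitats:
#' dominated by sand and the water column, with wall, substrate-patch and
#' cage categories each a few percent.
#'
#' @return Named numeric vector of 8 proportions summing to 1.
#' @export
default_habitat_composition <- function() {
  q <- c("sand" = 43, "water column" = 21, "tank wall" = 10, "pebble" = 7,
         "gravel" = 6, "vegetation" = 5, "cage wall" = 5, "cage floor" = 3)
  q / sum(q)
}

# Default treatment effects: competitor presence shifts the diet away from
# pelagic daphniids toward benthic prey and homogenises individuals (kappa
# up); predator exposure homogenises habitat use, an effect cancelled when
# the competitor is also present (interaction multiplier).
default_effects <- function() {
  list(
    competition = list(
      diet_shift = c("Ceriodaphnia spp." = -0.42, "Chydorus spp." = 0.18,
                     "Chironomidae larvae" = 0.18, "Ostracoda" = 0.10),
      habitat_shift = c("tank wall" = 0.09, "water column" = -0.08,
                        "cage wall" = -0.04, "pebble" = -0.04),
      kappa_mult = c(diet = 4, habitat = 1)),
    predation = list(
      diet_shift = numeric(0),
      habitat_shift = numeric(0),
      kappa_mult = c(diet = 1, habitat = 3)),
    interaction = list(
      kappa_mult = c(diet = 1, habitat = 1 / 3))
  )
}

#' Configuration for the synthetic mesocosm generator
#'
#' Bundles and validates all knobs of the Dirichlet-multinomial experiment
#' generator. Defaults emulate the structure of a 36-tank, 2x2
#' competition x predation-risk mesocosm study: 9 tanks per cell, 4 fish
#' per tank, 1-5 stomach samples per fish averaging ~4.3 diet items in
#' total, ~13.5 habitat scan observations per fish, 15% empty stomach
#' samples, and mortality-driven attrition that leaves some tanks below the
#' minimum-replication filter.
#'
#' @param n_tanks_per_cell Tanks per treatment cell (default 9).
#' @param n_fish_per_tank Fish stocked per tank (default 4).
#' @param diet_q,habitat_q Baseline compositions (named, sum to 1).
#' @param kappa_diet,kappa_habitat Dirichlet concentrations controlling
#'   individual preference heterogeneity (small kappa = strong
#'   specialisation, `Inf` = identical generalists).
#' @param effects Per-factor treatment effects: for `competition` and
#'   `predation`, a composition `diet_shift`/`habitat_shift` (named deltas
#'   applied on the simplex and renormalised) and a `kappa_mult` pair; for
#'   `interaction`, an extra `kappa_mult` applied only when both factors are
#'   present.
#' @param session_range Range (min, max) of stomach-sampling occasions per
#'   fish, drawn uniformly.
#' @param items_per_session_mean Poisson mean of diet items per non-empty
#'   sample.
#' @param empty_stomach_prob Probability a stomach sample is empty.
#' @param habitat_obs_mean Poisson mean of scheduled habitat scan sightings
#'   per fish; after mortality thinning the realised average is ~13.5.
#' @param mortality_prob Probability a fish dies during the experiment; a
#'   dead fish's sampling occasions are binomially thinned by its uniform
#'   survival fraction.
#' @param seed Default seed recorded in the config (can be overridden at
#'   generation time).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_tanks_per_cell = 9,
                             n_fish_per_tank = 4,
                             diet_q = default_diet_composition(),
                             habitat_q = default_habitat_composition(),
                             kappa_diet = 2,
                             kappa_habitat = 8,
                             effects = default_effects(),
                             session_range = c(1, 5),
                             items_per_session_mean = 1.7,
                             empty_stomach_prob = 0.15,
                             habitat_obs_mean = 15.4,
                             mortality_prob = 0.25,
                             seed = 1L) {
  stopifnot(n_tanks_per_cell >= 1, n_fish_per_tank >= 1)
  for (q in list(diet_q, habitat_q)) {
    if (any(q < 0) || abs(sum(q) - 1) > 1e-9 || is.null(names(q)))
      nv_stop("compositions must be named, non-negative and sum to 1",
              "nv_validation_error")
  }
  if (kappa_diet <= 0 || kappa_habitat <= 0)
    nv_stop("kappa must be positive (Inf allowed)", "nv_validation_error")
  for (p in c(empty_stomach_prob, mortality_prob))
    if (p < 0 || p > 1)
      nv_stop("probabilities must lie in [0, 1]", "nv_validation_error")
  structure(list(n_tanks_per_cell = n_tanks_per_cell,
                 n_fish_per_tank = n_fish_per_tank,
                 diet_q = diet_q, habitat_q = habitat_q,
                 kappa_diet = kappa_diet, kappa_habitat = kappa_habitat,
                 effects = effects, session_range = session_range,
                 items_per_session_mean = items_per_session_mean,
                 empty_stomach_prob = empty_stomach_prob,
                 habitat_obs_mean = habitat_obs_mean,
                 mortality_prob = mortality_prob, seed = seed),
            class = "generator_config")
}

#' Draw individual resource preferences
#'
#' Each individual's preference vector is drawn from a Dirichlet
#' distribution with mean `q` and concentration `kappa` (alpha = kappa * q),
#' so the marginal variance of category j is
#' \eqn{q_j (1 - q_j) / (\kappa + 1)}. `kappa = Inf` is a sentinel for
#' identical generalists: every preference equals `q` exactly. Categories
#' with q = 0 stay at 0.
#'
#' @param q Baseline composition (sums to 1).
#' @param kappa Positive concentration, or `Inf`.
#' @param n_fish Number of individuals.
#' @return n_fish x length(q) matrix of preference vectors (rows sum to 1).
#'   Uses the current RNG state.
#' @export
generate_individual_preferences <- function(q, kappa, n_fish) {
  if (any(q < 0) || abs(sum(q) - 1) > 1e-9)
    nv_stop("q must be a composition", "nv_validation_error")
  if (is.infinite(kappa))
    return(matrix(q, n_fish, length(q), byrow = TRUE,
                  dimnames = list(NULL, names(q))))
  if (kappa <= 0) nv_stop("kappa must be positive", "nv_validation_error")
  alpha <- kappa * q
  g <- matrix(stats::rgamma(n_fish * length(q), shape = rep(alpha, each = n_fish)),
              n_fish, length(q))
  g[, alpha == 0] <- 0
  out <- g / rowSums(g)
  colnames(out) <- names(q)
  out
}

# Apply a named shift vector on the simplex: add deltas, floor at 0,
# renormalise.
shift_composition <- function(q, shift) {
  if (length(shift) == 0L) return(q)
  unknown <- setdiff(names(shift), names(q))
  if (length(unknown) > 0L)
    nv_stop(paste0("shift names a category not in q: ",
                   paste(unknown, collapse = ", ")), "nv_validation_error")
  q[names(shift)] <- q[names(shift)] + shift
  q <- pmax(q, 0)
  q / sum(q)
}

#' Simulate one population's resource-use count matrix
#'
#' Draws individual preferences from a Dirichlet(kappa * q), then samples
#' each individual's counts as session-level multinomial draws. With
#' `kappa = Inf` this is exactly the stochastic-generalist null process:
#' every individual samples from the common composition q.
#'
#' @param q Population composition.
#' @param kappa Dirichlet concentration (`Inf` for generalists).
#' @param n_fish Individuals in the population.
#' @param session_range Range of sampling occasions per fish (uniform).
#' @param items_per_session_mean Poisson mean items per non-empty sample.
#' @param empty_stomach_prob Probability a sample is empty.
#' @return A `resource_matrix` (rows may be all-zero if every sample of a
#'   fish was empty). Uses the current RNG state.
#' @export
simulate_population <- function(q, kappa, n_fish = 4,
                                session_range = c(1, 5),
                                items_per_session_mean = 1.7,
                                empty_stomach_prob = 0.15) {
  prefs <- generate_individual_preferences(q, kappa, n_fish)
  k <- length(q)
  m <- matrix(0L, n_fish, k, dimnames = list(sprintf("f%02d", seq_len(n_fish)),
                                             names(q)))
  for (i in seq_len(n_fish)) {
    n_sess <- sample(seq(session_range[1L], session_range[2L]), 1L)
    for (s in seq_len(n_sess)) {
      if (stats::runif(1L) < empty_stomach_prob) next
      n_items <- stats::rpois(1L, items_per_session_mean)
      if (n_items == 0L) next
      m[i, ] <- m[i, ] + stats::rmultinom(1L, n_items, prefs[i, ])[, 1L]
    }
  }
  resource_matrix(m, tank_id = NA_character_, niche_kind = "diet")
}

#' Generate a complete synthetic mesocosm experiment
#'
#' Simulates long-format diet and habitat records for a full 2x2
#' competition x predation-risk experiment, together with the ground-truth
#' parameter ledger (per-tank composition and concentration, per-fish
#' preferences) needed for parameter-recovery tests. Treatment effects
#' modify each tank's composition (simplex shift) and concentration
#' (multiplicative), mortality thins late sampling occasions, and empty
#' stomach samples appear as zero-count records so downstream
#' empty-individual handling is exercised.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default: `config$seed`). The same config and
#'   seed always reproduce identical records.
#' @return List with `diet_records`, `habitat_records` (record
#'   data.frames as returned by [read_records()]), `design`
#'   ([experiment_design()] table) and `truth` (per-tank list of `q_diet`,
#'   `q_habitat`, `kappa_diet`, `kappa_habitat`, `pref_diet`,
#'   `pref_habitat`, `died`).
#' @export
generate_experiment <- function(config = generator_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cells <- expand.grid(competition = 0:1, predation = 0:1)
  n_tanks <- 4L * config$n_tanks_per_cell
  design <- experiment_design(
    sprintf("T%02d", seq_len(n_tanks)),
    rep(cells$competition, each = config$n_tanks_per_cell),
    rep(cells$predation, each = config$n_tanks_per_cell))

  diet_rows <- list(); hab_rows <- list(); truth <- list()
  for (t in seq_len(n_tanks)) {
    tank <- design$tank_id[t]
    comp <- design$competition[t] == 1L
    pred <- design$predation[t] == 1L
    eff <- config$effects
    q_d <- config$diet_q; q_h <- config$habitat_q
    k_d <- config$kappa_diet; k_h <- config$kappa_habitat
    if (comp) {
      q_d <- shift_composition(q_d, eff$competition$diet_shift)
      q_h <- shift_composition(q_h, eff$competition$habitat_shift)
      k_d <- k_d * eff$competition$kappa_mult[["diet"]]
      k_h <- k_h * eff$competition$kappa_mult[["habitat"]]
    }
    if (pred) {
      q_d <- shift_composition(q_d, eff$predation$diet_shift)
      q_h <- shift_composition(q_h, eff$predation$habitat_shift)
      k_d <- k_d * eff$predation$kappa_mult[["diet"]]
      k_h <- k_h * eff$predation$kappa_mult[["habitat"]]
    }
    if (comp && pred) {
      k_d <- k_d * eff$interaction$kappa_mult[["diet"]]
      k_h <- k_h * eff$interaction$kappa_mult[["habitat"]]
    }
    nf <- config$n_fish_per_tank
    pref_d <- generate_individual_preferences(q_d, k_d, nf)
    pref_h <- generate_individual_preferences(q_h, k_h, nf)
    died <- stats::runif(nf) < config$mortality_prob
    surv <- ifelse(died, stats::runif(nf), 1)

    for (i in seq_len(nf)) {
      fish <- sprintf("f%02d", i)
      # diet: 1-5 lavage sessions, thinned by survival fraction
      n_sess <- sample(seq(config$session_range[1L], config$session_range[2L]), 1L)
      n_sess <- stats::rbinom(1L, n_sess, surv[i])
      for (s in seq_len(n_sess)) {
        sess <- sprintf("s%02d", s)
        n_items <- if (stats::runif(1L) < config$empty_stomach_prob) 0L
                   else stats::rpois(1L, config$items_per_session_mean)
        if (n_items == 0L) {
          # empty sample: zero-count placeholder keeps the fish in the data
          diet_rows[[length(diet_rows) + 1L]] <- data.frame(
            tank_id = tank, individual_id = fish, session = sess,
            category = names(q_d)[1L], count = 0L)
          next
        }
        draw <- stats::rmultinom(1L, n_items, pref_d[i, ])[, 1L]
        nz <- draw > 0
        diet_rows[[length(diet_rows) + 1L]] <- data.frame(
          tank_id = tank, individual_id = fish,
          session = sess, category = names(q_d)[nz], count = draw[nz])
      }
      # habitat: Poisson number of scan sightings, one record each
      n_obs <- stats::rbinom(1L, stats::rpois(1L, config$habitat_obs_mean), surv[i])
      if (n_obs > 0L) {
        cats <- sample(names(q_h), n_obs, replace = TRUE, prob = pref_h[i, ])
        hab_rows[[length(hab_rows) + 1L]] <- data.frame(
          tank_id = tank, individual_id = fish,
          session = sprintf("o%03d", seq_len(n_obs)),
          category = cats, count = 1L)
      }
    }
    truth[[tank]] <- list(q_diet = q_d, q_habitat = q_h,
                          kappa_diet = k_d, kappa_habitat = k_h,
                          pref_diet = pref_d, pref_habitat = pref_h,
                          died = died)
  }
  list(diet_records = aggregate_records(do.call(rbind, diet_rows)),
       habitat_records = aggregate_records(do.call(rbind, hab_rows)),
       design = design, truth = truth, config = config, seed = seed)
}

#' Mean specialisation index across a concentration gradient
#'
#' Simulates replicate populations at each Dirichlet concentration kappa and
#' reports the mean observed 1 - WIC/TNW, the validation harness for
#' parameter recovery: the index must decrease as kappa grows (individuals
#' become interchangeable generalists).
#'
#' @param kappas Numeric vector (length >= 1) of concentrations.
#' @param n_reps Replicate populations per kappa (default 200).
#' @param q Population composition (default the diet baseline).
#' @param n_fish Individuals per population.
#' @param seed Optional seed.
#' @param ... Passed to [simulate_population()] (sampling-effort knobs).
#' @return data.frame (`kappa`, `mean_is_index`, `n_valid`) where `n_valid`
#'   counts replicates with a defined index (>= 2 non-empty individuals,
#'   >= 2 used categories).
#' @export
is_gradient_suite <- function(kappas, n_reps = 200,
                              q = default_diet_composition(),
                              n_fish = 4, seed = NULL, ...) {
  if (length(kappas) < 1L)
    nv_stop("need at least one kappa", "nv_validation_error")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(kappas, function(kap) {
    vals <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      m <- simulate_population(q, kap, n_fish = n_fish, ...)
      m <- drop_empty_individuals(m)$matrix
      if (nrow(m) >= 2L && ncol(m) >= 2L)
        vals[r] <- .is_index_counts(m)
    }
    data.frame(kappa = kap, mean_is_index = mean(vals, na.rm = TRUE),
               n_valid = sum(!is.na(vals)))
  })
  do.call(rbind, rows)
}
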