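#' Read long-format resource-use records
#'
#' Reads a CSV of per-sample resource-use observations (one row per
#' tank x individual x sampling session x resource category) and returns a
#' validated record table. Rows sharing the same
#' (tank, individual, session, category) key are summed, so repeated entries
#' for the same prey taxon within a stomach sample are merged.
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Named list mapping the required record fields
#'   (`tank_id`, `individual_id`, `session`, `category`, `count`) to the
#'   column names used in the file. Fields omitted from the list are assumed
#'   to use their default names. `count` may be omitted from the file
#'   entirely (e.g. habitat scan data where each row is one sighting), in
#'   which case every row contributes a count of 1.
#' @return A `data.frame` with columns `tank_id`, `individual_id`,
#'   `session`, `category` (character) and `count` (integer), one row per
#'   aggregated key.
#' @details Validation is strict: a missing mapped column is a schema error
#'   naming the column, and a negative or non-integer count is a validation
#'   error reporting the offending row number in the input file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(tank_id = "T1", individual_id = "f1", session = 1,
#'                      category = "chironomid", count = 2),
#'           f, row.names = FALSE)
#' read_records(f)
#' @seealso [build_matrix()], [apply_taxonomy()]
#' @export
read_records <- function(path, columns = list()) {
  defaults <- list(tank_id = "tank_id", individual_id = "individual_id",
                   session = "session", category = "category", count = "count")
  unknown <- setdiff(names(columns), names(defaults))
  if (length(unknown) > 0L)
    nv_stop(paste0("unknown column mapping field(s): ",
                   paste(unknown, collapse = ", ")), "nv_schema_error")
  cols <- utils::modifyList(defaults, columns)

  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("tank_id", "individual_id", "session", "category")
  for (field in required) {
    if (!cols[[field]] %in% names(raw))
      nv_stop(paste0("required column '", cols[[field]], "' (", field,
                     ") not found in ", path), "nv_schema_error")
  }

  counts <- if (cols$count %in% names(raw)) raw[[cols$count]] else rep(1L, nrow(raw))
  num <- suppressWarnings(as.numeric(counts))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad) > 0L)
    nv_stop(paste0("invalid count '", counts[bad[1L]], "' at data row ",
                   bad[1L], ": counts must be non-negative integers"),
            "nv_validation_error", rows = bad)

  records <- data.frame(
    tank_id = as.character(raw[[cols$tank_id]]),
    individual_id = as.character(raw[[cols$individual_id]]),
    session = as.character(raw[[cols$session]]),
    category = as.character(raw[[cols$category]]),
    count = as.integer(num),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(records$category)))
    nv_stop("empty resource category label", "nv_validation_error")
  aggregate_records(records)
}

# Sum counts over duplicate (tank, individual, session, category) keys.
aggregate_records <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    empty <- data.frame(tank_id = character(0), individual_id = character(0),
                        session = character(0), category = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
    return(empty)
  }
  agg <- stats::aggregate(count ~ tank_id + individual_id + session + category,
                          data = records, FUN = sum)
  agg <- agg[order(agg$tank_id, agg$individual_id, agg$session, agg$category), ]
  rownames(agg) <- NULL
  agg[, c("tank_id", "individual_id", "session", "category", "count")]
}

#' Aggregate raw taxa into analysis categories
#'
#' Replaces raw taxon labels with coarser analysis categories (e.g. pooling
#' chydorid subfamilies into a single genus-level group) and merges counts
#' that map to the same category. The total count is conserved.
#'
#' @param records Record table from [read_records()].
#' @param taxonomy Either a named character vector (`raw -> aggregated`) or a
#'   two-column data.frame (raw label, aggregated label). A raw label may
#'   appear only once.
#' @param strict If `TRUE` (default) an unmapped raw taxon is an error
#'   listing the offending labels; if `FALSE` unmapped taxa are pooled into
#'   the category `"other"`.
#' @return A record table with aggregated categories.
#' @examples
#' recs <- data.frame(tank_id = "T1", individual_id = "f1", session = "1",
#'                    category = c("Chydorinae", "Aloninae"), count = c(2L, 1L))
#' apply_taxonomy(recs, c(Chydorinae = "Chydorus spp.",
#'                        Aloninae = "Chydorus spp."))
#' @export
apply_taxonomy <- function(records, taxonomy, strict = TRUE) {
  if (is.data.frame(taxonomy)) {
    if (ncol(taxonomy) < 2L)
      nv_stop("taxonomy data.frame needs two columns (raw, aggregated)",
              "nv_schema_error")
    taxonomy <- stats::setNames(as.character(taxonomy[[2L]]),
                                as.character(taxonomy[[1L]]))
  }
  if (anyDuplicated(names(taxonomy)))
    nv_stop("taxonomy maps a raw taxon to more than one category",
            "nv_validation_error")
  unmapped <- setdiff(unique(records$category), names(taxonomy))
  if (length(unmapped) > 0L) {
    if (strict)
      nv_stop(paste0("unmapped taxa: ", paste(sort(unmapped), collapse = ", ")),
              "nv_taxonomy_error", unmapped = unmapped)
    taxonomy <- c(taxonomy, stats::setNames(rep("other", length(unmapped)), unmapped))
  }
  records$category <- unname(taxonomy[records$category])
  aggregate_records(records)
}

#' Read a taxonomy map from a two-column CSV
#'
#' @param path CSV file whose first column holds raw taxon labels and second
#'   column the aggregated category.
#' @return Named character vector usable by [apply_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    nv_stop("taxonomy CSV needs two columns (raw, aggregated)", "nv_schema_error")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Build an individuals x categories count matrix for one tank
#'
#' Sums counts over sampling sessions so each individual contributes a single
#' row of time-integrated resource use. Columns are ordered lexicographically
#' for reproducible serialisation. Individuals whose samples were all empty
#' (zero row total) are retained here and removed by
#' [drop_empty_individuals()].
#'
#' @param records Record table ([read_records()] output), possibly spanning
#'   several tanks.
#' @param tank_id Tank to extract.
#' @param niche_kind `"diet"` or `"habitat"`; stored as matrix metadata.
#' @return A `resource_matrix`: an integer matrix (individuals x categories)
#'   with attributes `tank_id` and `niche_kind`.
#' @export
build_matrix <- function(records, tank_id, niche_kind = c("diet", "habitat")) {
  niche_kind <- match.arg(niche_kind)
  sub <- records[records$tank_id == tank_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    nv_stop(paste0("no records for tank '", tank_id, "'"), "nv_empty_tank_error")
  inds <- sort(unique(sub$individual_id))
  cats <- sort(unique(sub$category))
  m <- matrix(0L, nrow = length(inds), ncol = length(cats),
              dimnames = list(inds, cats))
  idx <- cbind(match(sub$individual_id, inds), match(sub$category, cats))
  for (k in seq_len(nrow(sub)))
    m[idx[k, 1L], idx[k, 2L]] <- m[idx[k, 1L], idx[k, 2L]] + sub$count[k]
  resource_matrix(m, tank_id = tank_id, niche_kind = niche_kind)
}

#' Construct a resource-use matrix object
#'
#' @param m Non-negative integer matrix, individuals in rows, resource
#'   categories in columns, with dimnames.
#' @param tank_id Identifier of the population (tank).
#' @param niche_kind `"diet"` or `"habitat"`.
#' @return The matrix with class `resource_matrix`.
#' @export
resource_matrix <- function(m, tank_id = NA_character_,
                            niche_kind = c("diet", "habitat")) {
  niche_kind <- match.arg(niche_kind)
  m <- as.matrix(m)
  if (any(m < 0) || any(m != floor(m)))
    nv_stop("resource matrix cells must be non-negative integers",
            "nv_validation_error")
  storage.mode(m) <- "integer"
  structure(m, tank_id = tank_id, niche_kind = niche_kind,
            class = c("resource_matrix", class(m)))
}

#' @export
print.resource_matrix <- function(x, ...) {
  cat(sprintf("resource_matrix: tank '%s' (%s), %d individuals x %d categories\n",
              attr(x, "tank_id"), attr(x, "niche_kind"), nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

# Drop class/attributes when subsetting so downstream matrix algebra is plain.
#' @export
`[.resource_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, tank_id = attr(x, "tank_id"),
                     niche_kind = attr(x, "niche_kind"),
                     class = class(x))
  out
}

#' Remove individuals never sampled with any resource items
#'
#' Individuals only ever captured with empty stomachs (all-zero rows) carry
#' no niche information and are removed before analysis; categories that
#' become unused (all-zero columns) are removed with them.
#'
#' @param m A `resource_matrix`.
#' @return List with elements `matrix` (the pruned `resource_matrix`) and
#'   `n_dropped` (number of individuals removed).
#' @export
drop_empty_individuals <- function(m) {
  keep_r <- rowSums(m) > 0
  out <- m[keep_r, , drop = FALSE]
  keep_c <- colSums(out) > 0
  out <- out[, keep_c, drop = FALSE]
  list(matrix = out, n_dropped = sum(!keep_r))
}

#' Apply the minimum-replication tank filter
#'
#' A population (tank) is analysable only if enough individuals were sampled
#' deeply enough: it is retained when at least `min_individuals` individuals
#' each have at least `min_measures` niche measures (diet items or habitat
#' observations, i.e. the matrix row sum). Individuals below the per-fish
#' threshold are not removed from retained tanks; the rule only gates which
#' tanks enter the analysis.
#'
#' @param matrices Named list of `resource_matrix` objects, one per tank.
#' @param min_individuals Minimum number of adequately sampled individuals.
#' @param min_measures Minimum row sum for an individual to count as
#'   adequately sampled.
#' @return List with `retained` (list of matrices) and `exclusions`
#'   (data.frame with `tank_id` and `reason`).
#' @export
filter_tanks <- function(matrices, min_individuals = 3, min_measures = 3) {
  keep <- logical(length(matrices))
  reasons <- character(0)
  tanks <- character(0)
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    n_ok <- sum(rowSums(m) >= min_measures)
    if (n_ok >= min_individuals) {
      keep[i] <- TRUE
    } else {
      tanks <- c(tanks, attr(m, "tank_id"))
      reasons <- c(reasons, sprintf(
        "only %d of %d individuals have >= %d measures (need >= %d)",
        n_ok, nrow(m), min_measures, min_individuals))
    }
  }
  list(retained = matrices[keep],
       exclusions = data.frame(tank_id = tanks, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Mean resource composition of a population
#'
#' Each individual's counts are first converted to proportions, and the
#' proportions are then averaged with equal weight per individual, so a
#' heavily sampled fish does not dominate the tank mean.
#'
#' @param m A `resource_matrix` with positive row sums.
#' @return Named numeric vector of category proportions summing to 1.
#' @export
tank_mean_composition <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    nv_stop("cannot average an empty matrix", "nv_empty_tank_error")
  if (any(rowSums(m) == 0))
    nv_stop("matrix has all-zero rows; call drop_empty_individuals() first",
            "nv_validation_error")
  p <- unclass(m) / rowSums(m)
  colMeans(p)
}

#' Define the 2x2 experimental design
#'
#' Maps each tank to its cell of the competition x predation-risk factorial
#' and assigns the conventional treatment label.
#'
#' @param tank_id Character vector of tank identifiers (unique).
#' @param competition,predation Binary (0/1 or logical) treatment flags.
#' @return A data.frame with columns `tank_id`, `competition`, `predation`
#'   (integer 0/1) and `treatment` (factor with levels control, predation,
#'   competition, predation+competition).
#' @export
experiment_design <- function(tank_id, competition, predation) {
  tank_id <- as.character(tank_id)
  if (anyDuplicated(tank_id))
    nv_stop("duplicated tank_id in design", "nv_validation_error")
  competition <- as.integer(competition)
  predation <- as.integer(predation)
  if (any(!competition %in% 0:1) || any(!predation %in% 0:1))
    nv_stop("treatment flags must be 0/1", "nv_validation_error")
  lab <- c("control", "predation", "competition", "predation+competition")
  treatment <- lab[1L + predation + 2L * competition]
  data.frame(tank_id = tank_id, competition = competition,
             predation = predation,
             treatment = factor(treatment, levels = lab),
             stringsAsFactors = FALSE)
}

#' Read a 2x2 design from CSV
#'
#' @param path CSV with columns `tank_id`, `competition`, `predation`.
#' @return See [experiment_design()].
#' @export
read_design <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("tank_id", "competition", "predation"))
    if (!col %in% names(tab))
      nv_stop(paste0("design CSV is missing column '", col, "'"),
              "nv_schema_error")
  experiment_design(tab$tank_id, tab$competition, tab$predation)
}
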