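test_that("read_records parses, sums duplicate keys and validates counts", {
  path <- write_records_csv(toy_records())
  recs <- read_records(path)
  expect_s3_class(recs, "data.frame")
  expect_equal(nrow(recs), 4L)
  expect_type(recs$count, "integer")

  dup <- toy_records()
  dup <- rbind(dup, data.frame(tank_id = "T1", individual_id = "A",
                               session = "s1", category = "chironomid",
                               count = 3L))
  recs <- read_records(write_records_csv(dup))
  expect_equal(recs$count[recs$individual_id == "A" & recs$session == "s1" &
                            recs$category == "chironomid"], 5L)

  bad <- toy_records(); bad$count[2] <- -1L
  expect_error(read_records(write_records_csv(bad)), class = "nv_validation_error")
  expect_error(read_records(write_records_csv(bad)), "row 2")

  frac <- toy_records(); frac$count <- frac$count + 0.5
  expect_error(read_records(write_records_csv(frac)), class = "nv_validation_error")
})

test_that("read_records supports column mapping and implicit count of 1", {
  df <- data.frame(tank = "T1", fish = "A", date = "d1", habitat = "sand")
  path <- write_records_csv(df)
  recs <- read_records(path, columns = list(tank_id = "tank",
                                            individual_id = "fish",
                                            session = "date",
                                            category = "habitat"))
  expect_equal(recs$count, 1L)
  expect_error(read_records(path), class = "nv_schema_error")
  expect_error(read_records(path, columns = list(tank_id = "missing_col",
                                                 individual_id = "fish",
                                                 session = "date",
                                                 category = "habitat")),
               "missing_col")
})

test_that("apply_taxonomy pools subfamilies and conserves counts", {
  recs <- data.frame(tank_id = "T1", individual_id = "f1", session = "s1",
                     category = c("Chydorinae", "Aloninae"), count = c(2L, 1L),
                     stringsAsFactors = FALSE)
  out <- apply_taxonomy(recs, c(Chydorinae = "Chydorus spp.",
                                Aloninae = "Chydorus spp."))
  expect_equal(out$category, "Chydorus spp.")
  expect_equal(out$count, 3L)

  orig <- toy_records()
  ident <- apply_taxonomy(orig, c(chironomid = "chironomid",
                                  ostracod = "ostracod"))
  key <- function(x) x[order(x$individual_id, x$session, x$category), ]
  expect_equal(unname(as.matrix(key(ident))), unname(as.matrix(key(orig))))
  expect_equal(sum(ident$count), sum(orig$count))

  recs$category[1] <- "Hydra"
  expect_error(apply_taxonomy(recs, c(Aloninae = "Chydorus spp.")), "Hydra")
  lax <- apply_taxonomy(recs, c(Aloninae = "Chydorus spp."), strict = FALSE)
  expect_true("other" %in% lax$category)
  expect_equal(sum(lax$count), sum(recs$count))
})

test_that("build_matrix sums over sessions with deterministic column order", {
  m <- build_matrix(toy_records(), "T1", "diet")
  expect_s3_class(m, "resource_matrix")
  expect_equal(colnames(m), c("chironomid", "ostracod"))
  expect_equal(unclass(m)["A", ], c(chironomid = 3L, ostracod = 1L))
  expect_equal(sum(m), sum(toy_records()$count))  # conservation
  expect_error(build_matrix(toy_records(), "T9", "diet"),
               class = "nv_empty_tank_error")

  one <- toy_records()[4, ]
  m1 <- build_matrix(one, "T1", "diet")
  expect_equal(dim(m1), c(1L, 1L))

  # two fish with disjoint prey -> zeros off-diagonal
  disj <- data.frame(tank_id = "T1", individual_id = c("A", "B"),
                     session = "s1", category = c("a", "b"), count = 2L)
  m2 <- build_matrix(disj, "T1", "diet")
  expect_equal(unname(unclass(m2)), matrix(c(2L, 0L, 0L, 2L), 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("drop_empty_individuals removes zero rows and orphaned columns", {
  m <- resource_matrix(matrix(c(2, 0, 0, 1, 0, 0, 0, 3), 4, 2,
                              dimnames = list(letters[1:4], c("x", "y"))),
                       tank_id = "T1")
  out <- drop_empty_individuals(m)
  expect_equal(out$n_dropped, 2L)
  expect_equal(nrow(out$matrix), 2L)

  full <- resource_matrix(matrix(1:4, 2, 2, dimnames = list(c("a", "b"),
                                                            c("x", "y"))))
  out2 <- drop_empty_individuals(full)
  expect_equal(out2$n_dropped, 0L)
  expect_equal(unclass(out2$matrix), unclass(full))

  none <- resource_matrix(matrix(0L, 2, 2, dimnames = list(c("a", "b"),
                                                           c("x", "y"))))
  out3 <- drop_empty_individuals(none)
  expect_equal(out3$n_dropped, 2L)
  expect_equal(nrow(out3$matrix), 0L)
})

test_that("filter_tanks applies the 3-fish/3-measure rule and is idempotent", {
  mk <- function(rowsums, id) {
    m <- matrix(0L, length(rowsums), 2,
                dimnames = list(sprintf("f%d", seq_along(rowsums)), c("x", "y")))
    m[, 1] <- as.integer(rowsums)
    m[1, 2] <- 0L
    resource_matrix(m, tank_id = id)
  }
  mats <- list(ok = mk(c(5, 4, 3), "ok"), short = mk(c(5, 4, 2), "short"),
               few = mk(c(9, 9), "few"))
  out <- filter_tanks(mats)
  expect_equal(names(out$retained), "ok")
  expect_setequal(out$exclusions$tank_id, c("short", "few"))

  again <- filter_tanks(out$retained)
  expect_equal(names(again$retained), names(out$retained))
  expect_equal(nrow(again$exclusions), 0L)
})

test_that("tank mean composition averages individual proportions equally", {
  m <- resource_matrix(matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(tank_mean_composition(m), c(x = 0.5, y = 0.5))

  m2 <- resource_matrix(matrix(c(1, 1, 3, 1), 2, 2, byrow = TRUE,
                               dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(tank_mean_composition(m2), c(x = 0.625, y = 0.375))

  single <- resource_matrix(matrix(c(3, 1), 1, 2,
                                   dimnames = list("a", c("x", "y"))))
  expect_equal(tank_mean_composition(single), c(x = 0.75, y = 0.25))

  # proportion-first averaging: scaling one individual's counts is a no-op,
  # and the output always sums to 1
  set.seed(31)
  for (rep in 1:20) {
    m <- resource_matrix(random_count_matrix(4, 5))
    v <- tank_mean_composition(m)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    m_scaled <- unclass(m); m_scaled[2, ] <- m_scaled[2, ] * 7L
    expect_equal(tank_mean_composition(resource_matrix(m_scaled)), v)
  }

  empty <- drop_empty_individuals(
    resource_matrix(matrix(0L, 1, 1, dimnames = list("a", "x"))))$matrix
  expect_error(tank_mean_composition(empty), class = "nv_empty_tank_error")
})

test_that("experiment_design assigns consistent treatment labels", {
  d <- experiment_design(c("T1", "T2", "T3", "T4"), c(0, 0, 1, 1),
                         c(0, 1, 0, 1))
  expect_equal(as.character(d$treatment),
               c("control", "predation", "competition",
                 "predation+competition"))
  expect_error(experiment_design(c("T1", "T1"), c(0, 1), c(0, 1)),
               class = "nv_validation_error")
  expect_error(experiment_design("T1", 2, 0), class = "nv_validation_error")
})
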