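# Runtime conformance checking and the initial time window.

test_that("a conformant trace and the empty dataset validate cleanly", {
  d <- quick_dataset(conformant_toy_slice("S1", 0),
                     conformant_toy_slice("S2", 10000))
  expect_identical(nrow(validate_trace(d)), 0L)
  expect_identical(nrow(validate_trace(quick_dataset())), 0L)
})

test_that("slice disjointness (T1) and master shape (T2) are checked", {
  s1 <- conformant_toy_slice("S1", 0)
  s2 <- conformant_toy_slice("S2", 10000)
  s2$instances[[3]]$instance_id <- "S1-01"      # id reused across slices
  d <- medmod_dataset(toy_model(), list(s1, s2))
  expect_true("T1" %in% validate_trace(d)$rule)

  s3 <- medmod_slice("S1", list(                # no master instance at all
    medmod_instance("S1-01", "Diagnose", 0, 10,
                    list(diagnosis = "Flu"))))
  v <- validate_trace(quick_dataset(s3))
  expect_true("T2" %in% v$rule)

  s4 <- conformant_toy_slice("S1", 0)           # master with a cause
  s4$instances[[1]]$caused_by <- list(instance = "S1-02", kind = "follows")
  expect_true("T2" %in% validate_trace(quick_dataset(s4))$rule)
})

test_that("causal links must match model edges (T3); dangling ids are structural", {
  s <- conformant_toy_slice("S1", 0)
  s$instances[[5]]$caused_by$kind <- "follows"  # no follows Stay->Discharge
  expect_true("T3" %in% validate_trace(quick_dataset(s))$rule)

  s2 <- conformant_toy_slice("S1", 0)
  s2$instances[[3]]$caused_by$instance <- "S1-99"
  expect_error(validate_trace(quick_dataset(s2)),
               class = "medmod_structural_error")
})

test_that("follows timing (T4) and the XOR successor rule (T5) are checked", {
  s <- conformant_toy_slice("S1", 0)
  s$instances[[2]]$start <- 50                  # Stay starts before Visit ends
  expect_true("T4" %in% validate_trace(quick_dataset(s))$rule)

  # an open-ended predecessor is flagged as a warning, not a violation
  s2 <- conformant_toy_slice("S1", 0)
  s2$instances[[1]]$end <- NA_real_
  v2 <- validate_trace(quick_dataset(s2))
  expect_identical(unique(v2$severity[v2$rule == "T4"]), "warning")

  # two follows-successors of the same instance
  s3 <- conformant_toy_slice("S1", 0)
  s3$instances <- c(s3$instances, list(
    medmod_instance("S1-06", "Stay", 300, 400,
                    caused_by = list(instance = "S1-01", kind = "follows"))))
  expect_true("T5" %in% validate_trace(quick_dataset(s3))$rule)
})

test_that("composition cardinalities (T6) and interruption timing (T7) are checked", {
  m <- toy_model()
  m$edges[[2]]$cardinality <- "1"               # Stay must hold 1 Diagnose
  s <- conformant_toy_slice("S1", 0)
  s$instances <- c(s$instances, list(
    medmod_instance("S1-06", "Diagnose", 800, 900,
                    list(diagnosis = "Other"),
                    caused_by = list(instance = "S1-02",
                                     kind = "composition"))))
  d <- medmod_dataset(m, list(s))
  expect_true("T6" %in% validate_trace(d)$rule)

  # a component born after the interrupting instance started
  s2 <- conformant_toy_slice("S1", 0)
  s2$instances <- c(s2$instances, list(
    medmod_instance("S1-06", "Diagnose", 1700, 1800,
                    list(diagnosis = "Late"),
                    caused_by = list(instance = "S1-02",
                                     kind = "composition"))))
  v <- validate_trace(quick_dataset(s2))
  expect_identical(v$rule[v$severity == "error"], "T7")
  expect_identical(v$element[v$rule == "T7"], "S1-06")
})

test_that("attribute typing and enumeration membership (T8) are checked", {
  s <- conformant_toy_slice("S1", 0)
  s$instances[[1]]$attrs$age <- 30.5             # fractional Integer
  expect_true("T8" %in% validate_trace(quick_dataset(s))$rule)

  s2 <- conformant_toy_slice("S1", 0)
  s2$instances[[2]]$attrs$unit <- "Z"            # not a literal of 'ward'
  expect_true("T8" %in% validate_trace(quick_dataset(s2))$rule)

  s3 <- conformant_toy_slice("S1", 0)
  s3$instances[[1]]$attrs$height <- 180          # undeclared attribute
  expect_true("T8" %in% validate_trace(quick_dataset(s3))$rule)

  # absent values are permitted, not violations
  s4 <- conformant_toy_slice("S1", 0)
  s4$instances[[1]]$attrs$age <- NULL
  expect_identical(nrow(validate_trace(quick_dataset(s4))), 0L)
})

test_that("the initial dataset selects whole slices by a half-open window", {
  day <- 86400
  d <- quick_dataset(conformant_toy_slice("A", 1 * day),
                     conformant_toy_slice("B", 5 * day),
                     conformant_toy_slice("C", 9 * day))
  # window [day 4, day 9) catches only the day-5 transaction
  w <- build_initial_dataset(d, 4 * day, 9 * day)
  expect_identical(slice_ids(w), "B")
  # the right edge is exclusive, the left edge inclusive
  expect_identical(slice_ids(build_initial_dataset(d, 5 * day, 9 * day)),
                   "B")
  expect_identical(slice_ids(build_initial_dataset(d, 4 * day + 1, 5 * day)),
                   character(0))
  # identity window and empty window
  expect_same_dataset(build_initial_dataset(d, 0, 10 * day), d)
  expect_identical(n_slices(build_initial_dataset(d, 20 * day, 30 * day)), 0L)
  # inverted window is an argument error
  expect_error(build_initial_dataset(d, 9 * day, 4 * day),
               class = "medmod_argument_error")
})

test_that("window selection is idempotent and disjoint windows partition the slices", {
  set.seed(404)
  d <- simulate_trace(demo_model(), demo_config(30, seed = 404))
  starts <- vapply(d$slices, function(s) s$instances[[1]]$start, numeric(1))
  lo <- min(starts); hi <- max(starts) + 1
  cuts <- sort(c(lo, hi, stats::runif(3, lo, hi)))
  got <- character(0)
  for (k in seq_len(length(cuts) - 1)) {
    w <- build_initial_dataset(d, cuts[k], cuts[k + 1])
    w2 <- build_initial_dataset(w, cuts[k], cuts[k + 1])
    expect_same_dataset(w, w2)
    expect_true(all(slice_ids(w) %in% slice_ids(d)))
    got <- c(got, slice_ids(w))
  }
  expect_identical(sort(got), slice_ids(d))  # each slice in exactly one window
})
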