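# Filtering, partitioning, retrieval: spec'd worked examples with frozen
# expected sets, plus resolution/typing errors.

# three clinic slices with distinguishable diagnoses and costs
three_slices <- function() {
  s1 <- quick_slice("S1",
    inst("Visit", 0, 100, age = 5, surname = "Smith"),
    inst("Diagnose", 200, 300, diagnosis = "Chickenpox"),
    inst("Procedure", 400, 500, code = "XR", cost = 80),
    inst("Procedure", 600, 700, code = "CT", cost = 140))
  s2 <- quick_slice("S2",
    inst("Visit", 0, 100, age = 40, surname = "Jones"),
    inst("Diagnose", 200, 300, diagnosis = "Pneumonia"),
    inst("Diagnose", 350, 380, diagnosis = "Stroke"),
    inst("Procedure", 400, 500, code = "XR", cost = 90))
  s3 <- quick_slice("S3",
    inst("Visit", 0, 100, age = 12, surname = "Smith"),
    inst("Diagnose", 200, 300, diagnosis = "Pneumonia"))
  quick_dataset(s1, s2, s3)
}

test_that("comparison conditions keep exactly the slices containing a matching instance", {
  d <- three_slices()
  f <- evaluate_comparison(d, pql_comparison("Diagnose", "diagnosis", "=",
                                             "Chickenpox"))
  expect_identical(slice_ids(f), "S1")
  # the matching slice keeps all its instances
  expect_identical(length(f$slices$S1$instances), 4L)

  # age > 67 on a pediatric-style dataset: nothing matches
  f2 <- evaluate_comparison(d, pql_comparison("Visit", "age", ">", 67))
  expect_identical(n_slices(f2), 0L)

  # unsatisfiable two-term conjunction is always empty
  f3 <- evaluate_comparison(d, pql_comparison("Visit", "age", ">", 6,
                                              combine = "AND",
                                              op2 = "<", value2 = 6))
  expect_identical(n_slices(f3), 0L)

  # the OR form recovers both branches
  f4 <- evaluate_comparison(d, pql_comparison("Visit", "age", "<", 6,
                                              combine = "OR",
                                              op2 = ">", value2 = 30))
  expect_identical(slice_ids(f4), c("S1", "S2"))

  # string operators
  f5 <- evaluate_comparison(d, pql_comparison("Visit", "surname",
                                              "begins_with", "Sm"))
  expect_identical(slice_ids(f5), c("S1", "S3"))
  f6 <- evaluate_comparison(d, pql_comparison("Visit", "surname",
                                              "contains", "one"))
  expect_identical(slice_ids(f6), "S2")
})

test_that("comparisons against absent values are false; the count target works", {
  s <- quick_slice("S1",
    inst("Visit", 0, 100, surname = "NoAge"),
    inst("Diagnose", 200, 300, diagnosis = "Flu"))
  d <- quick_dataset(s)
  f <- evaluate_comparison(d, pql_comparison("Visit", "age", "<", 200))
  expect_identical(n_slices(f), 0L)

  d2 <- three_slices()
  f2 <- evaluate_comparison(d2, pql_comparison("Diagnose", "count", ">", 1))
  expect_identical(slice_ids(f2), "S2")
})

test_that("resolution and type errors are classed conditions", {
  d <- three_slices()
  expect_error(evaluate_comparison(d, pql_comparison("Ghost", "age", ">", 1)),
               class = "medmod_resolution_error")
  expect_error(evaluate_comparison(d, pql_comparison("Visit", "ghost", ">", 1)),
               class = "medmod_resolution_error")
  expect_error(evaluate_comparison(d, pql_comparison("Visit", "age",
                                                     "contains", "x")),
               class = "medmod_type_error")
  expect_error(evaluate_comparison(d, pql_comparison("Visit", "surname",
                                                     ">", "x")),
               class = "medmod_type_error")
  expect_error(evaluate_comparison(d, pql_comparison("Visit", "age", ">",
                                                     "ten")),
               class = "medmod_type_error")
})

test_that("slice aggregates follow the empty-aggregate rule and exact arithmetic", {
  d <- three_slices()
  # S1 costs {80, 140}: average 110 > 100 -> retained; S2 average 90 fails;
  # S3 has no Procedure instances -> fails
  f <- evaluate_slice_aggregate(d, pql_aggregate("Procedure", "Average",
                                                 ">", 100,
                                                 attribute = "cost"))
  expect_identical(slice_ids(f), "S1")

  # Count boundary: 'happened more than once'
  f2 <- evaluate_slice_aggregate(d, pql_aggregate("Diagnose", "Count",
                                                  ">", 1))
  expect_identical(slice_ids(f2), "S2")

  # Sum >= 0 still fails for slices without instances of the activity
  f3 <- evaluate_slice_aggregate(d, pql_aggregate("Procedure", "Sum",
                                                  ">=", 0,
                                                  attribute = "cost"))
  expect_identical(slice_ids(f3), c("S1", "S2"))

  # instances present but all values absent: Sum/Average fail too
  s <- quick_slice("S9",
    inst("Visit", 0, 100),
    inst("Procedure", 200, 300, code = "XR"))
  f4 <- evaluate_slice_aggregate(quick_dataset(s),
                                 pql_aggregate("Procedure", "Sum", ">=", 0,
                                               attribute = "cost"))
  expect_identical(n_slices(f4), 0L)
  # ... but Count sees them
  f5 <- evaluate_slice_aggregate(quick_dataset(s),
                                 pql_aggregate("Procedure", "Count", "=", 1))
  expect_identical(slice_ids(f5), "S9")
})

test_that("partitioning ranks by per-slice extremes with slice-id tie-breaks", {
  mk <- function(id, exp) quick_slice(id,
    inst("Visit", 0, 100),
    inst("Stay", 200, 300, total_expenses = exp,
         id = paste0(id, "-stay")))
  d <- quick_dataset(mk("A", 10), mk("B", 50), mk("C", 30), mk("D", 50),
                     mk("E", 20))
  top2 <- evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                              "Top", 2))
  expect_identical(slice_ids(top2), c("B", "D"))  # tie on 50 broken by id

  bot1 <- evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                              "Bottom", 1))
  expect_identical(slice_ids(bot1), "A")

  # k saturates at the number of ranked slices
  all5 <- evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                              "Top", 50))
  expect_identical(n_slices(all5), 5L)

  expect_error(evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                                   "Top", 0)),
               class = "medmod_argument_error")
  expect_error(evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                                   "Top", 101)),
               class = "medmod_argument_error")
  # a looser configured bound admits larger k
  expect_identical(
    n_slices(evaluate_partition(d, pql_partition("Stay", "total_expenses",
                                                 "Top", 101),
                                k_max = 200L)), 5L)
})

test_that("retrieval aggregates and the instance table agree with hand arithmetic", {
  d <- three_slices()
  expect_identical(retrieve_aggregate(d, "Procedure", "Count"), 3)
  expect_identical(retrieve_aggregate(d, "Procedure", "Sum", "cost"),
                   80 + 140 + 90)
  expect_equal(retrieve_aggregate(d, "Procedure", "Average", "cost"),
               (80 + 140 + 90) / 3)
  # empty dataset: Count 0, Sum 0, Average undefined
  e <- quick_dataset()
  expect_identical(retrieve_aggregate(e, "Procedure", "Count"), 0)
  expect_identical(retrieve_aggregate(e, "Procedure", "Sum", "cost"), 0)
  expect_true(is.na(retrieve_aggregate(e, "Procedure", "Average", "cost")))

  tab <- instance_table(d, "Procedure")
  expect_identical(nrow(tab), 3L)
  expect_identical(names(tab)[1:4],
                   c("slice_id", "instance_id", "start_time", "end_time"))
  expect_identical(names(tab)[5:7], c("code", "cost", "when"))
  expect_identical(sort(unique(tab$slice_id)), c("S1", "S2"))
  # header-only table for an activity with no instances
  tab2 <- instance_table(d, "Discharge")
  expect_identical(nrow(tab2), 0L)
  expect_identical(names(tab2),
                   c("slice_id", "instance_id", "start_time", "end_time"))
  # row count ties out with Count retrieval
  expect_identical(nrow(tab), as.integer(retrieve_aggregate(d, "Procedure",
                                                            "Count")))
})

test_that("implication probability divides the two slice counts", {
  mk <- function(id, ...) {
    dgs <- list(...)
    args <- c(list(id, inst("Visit", 0, 100, age = 50)),
              lapply(seq_along(dgs), function(k)
                inst("Diagnose", 100 * k + 100, 100 * k + 150,
                     diagnosis = dgs[[k]])))
    do.call(quick_slice, args)
  }
  d <- quick_dataset(mk("P1", "Pneumonia"), mk("P2", "Pneumonia"),
                     mk("P3", "Pneumonia"),
                     mk("P4", "Pneumonia", "Stroke"),
                     mk("S5", "Stroke"))
  condA <- pql_comparison("Diagnose", "diagnosis", "=", "Pneumonia")
  condB <- pql_comparison("Diagnose", "diagnosis", "=", "Stroke")
  expect_identical(implication_probability(d, condA, condB), 1 / 4)
  expect_identical(implication_probability(d, condA, condA), 1)
  none <- pql_comparison("Diagnose", "diagnosis", "=", "Gout")
  expect_true(is.na(implication_probability(d, none, condB)))
})

test_that("apply_query composes conditions, partitions, and retrievals", {
  d <- three_slices()
  # identity query: dataset unchanged, counts are the raw counts
  r0 <- apply_query(d, pql_query())
  expect_same_dataset(r0$dataset, d)
  expect_identical(unname(r0$counts[c("Visit", "Diagnose", "Procedure")]),
                   c(3, 4, 3))
  expect_identical(r0$inspection_count, 0L)

  # Pneumonia then Stroke: conjunction at the slice level
  q <- pql_query(conditions = list(
    pql_comparison("Diagnose", "diagnosis", "=", "Pneumonia"),
    pql_comparison("Diagnose", "diagnosis", "=", "Stroke")))
  expect_identical(slice_ids(apply_query(d, q)$dataset), "S2")

  # disjoint partitions intersect to nothing (oldest vs youngest patient)
  q2 <- pql_query(partitions = list(
    pql_partition("Visit", "age", "Top", 1),
    pql_partition("Visit", "age", "Bottom", 1)))
  expect_identical(n_slices(apply_query(d, q2)$dataset), 0L)

  # retrievals are computed on the filtered dataset
  q3 <- pql_query(
    conditions = list(pql_comparison("Diagnose", "diagnosis", "=",
                                     "Pneumonia")),
    retrievals = list(pql_retrieval("sum", "Procedure", "cost"),
                      pql_retrieval("table", "Diagnose")))
  r3 <- apply_query(d, q3)
  expect_identical(r3$aggregates[[1]]$value, 90)
  expect_identical(nrow(r3$tables$Diagnose), 3L)
})
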