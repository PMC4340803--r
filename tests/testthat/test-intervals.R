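# Time intervals (derived slice attributes) and grouping of slices.

hm <- function(h, m = 0) h * 3600 + m * 60   # seconds-of-day shorthand

test_that("interval pairing honors the matching condition", {
  # assignment at 10:00 carries code X; executions at 11:00 (code Y) and
  # 12:30 (code X): with code pairing the single value is 10:00 -> 12:30
  s <- quick_slice("S1",
    inst("Visit", 0, 100),
    inst("Procedure", hm(10), hm(10, 30), code = "X", when = hm(10)),
    inst("Procedure", hm(11), hm(11, 30), code = "Y", when = hm(11)),
    inst("Procedure", hm(12, 30), hm(13), code = "X", when = hm(12, 30)))
  idef <- pql_interval("wait", "Procedure", "Procedure",
                       start_attribute = "when", end_attribute = "when",
                       pairing = c("code", "code"))
  # self-pairing is excluded, so the 10:00 start must reach the 12:30 end
  expect_identical(compute_intervals(s, idef, toy_model()), 9000)
})

test_that("default pairing is adjacent-in-time with non-negative durations", {
  s <- quick_slice("S1",
    inst("Visit", 0, 50),
    inst("Diagnose", hm(9), hm(9, 10), when = hm(9)),
    inst("Diagnose", hm(10), hm(10, 10), when = hm(10)),
    inst("Procedure", hm(9, 30), hm(9, 40), when = hm(9, 30)),
    inst("Procedure", hm(10, 30), hm(10, 40), when = hm(10, 30)))
  idef <- pql_interval("d2p", "Diagnose", "Procedure",
                       start_attribute = "when", end_attribute = "when")
  expect_identical(compute_intervals(s, idef, toy_model()), c(1800, 1800))

  # identical timestamps give a zero-length interval
  s2 <- quick_slice("S2",
    inst("Visit", 0, 50),
    inst("Diagnose", hm(9), hm(9, 10), when = hm(9)),
    inst("Procedure", hm(9), hm(9, 40), when = hm(9)))
  expect_identical(compute_intervals(s2, idef, toy_model()), 0)

  # intrinsic start times are the default endpoints
  idef2 <- pql_interval("v2d", "Visit", "Diagnose")
  expect_identical(compute_intervals(s2, idef2, toy_model()), hm(9))

  # non-DateTime endpoints are type errors
  expect_error(
    compute_intervals(s2, pql_interval("bad", "Diagnose", "Procedure",
                                       start_attribute = "diagnosis"),
                      toy_model()),
    class = "medmod_type_error")
})

test_that("interval values become filterable derived attributes in a query", {
  mk <- function(id, gap) quick_slice(id,
    inst("Visit", 0, 50),
    inst("Diagnose", hm(9), hm(9, 10), when = hm(9)),
    inst("Procedure", hm(9) + gap, hm(9) + gap + 600, when = hm(9) + gap))
  d <- quick_dataset(mk("A", 1800), mk("B", 7200), mk("C", 3600))
  q <- pql_query(
    intervals = list(pql_interval("d2p", "Diagnose", "Procedure",
                                  start_attribute = "when",
                                  end_attribute = "when")),
    conditions = list(pql_comparison("Visit", "d2p", ">", 3000)))
  r <- apply_query(d, q)
  expect_identical(slice_ids(r$dataset), c("B", "C"))
  expect_identical(r$intervals$d2p$B, 7200)
})

test_that("grouping merges slices on a shared key and keeps singletons", {
  mk <- function(id, surname) quick_slice(id,
    inst("Visit", 0, 50, surname = surname),
    inst("Diagnose", 100, 150, diagnosis = "Flu"))
  d <- quick_dataset(mk("A", "Smith"), mk("B", "Jones"), mk("C", "Smith"))
  g <- group_slices(d, pql_grouping("Visit", "surname"))
  expect_identical(n_slices(g), 2L)
  expect_identical(sort(slice_ids(g)), c("group:Jones", "group:Smith"))
  expect_identical(length(g$slices[["group:Smith"]]$instances), 4L)
  expect_identical(n_instances(g), n_instances(d))

  # all keys distinct: output isomorphic to input (ids re-keyed)
  d2 <- quick_dataset(mk("A", "Smith"), mk("B", "Jones"))
  g2 <- group_slices(d2, pql_grouping("Visit", "surname"))
  expect_identical(n_slices(g2), 2L)
  expect_identical(vapply(g2$slices, function(s) length(s$instances),
                          integer(1), USE.NAMES = FALSE), c(2L, 2L))

  # a slice with two key values joins only its earliest key's group
  s <- quick_slice("X",
    inst("Visit", 0, 50, surname = "Smith"),
    inst("Visit", 100, 150, surname = "Jones"),
    inst("Diagnose", 200, 250, diagnosis = "Flu"))
  d3 <- quick_dataset(s, mk("A", "Smith"), mk("B", "Jones"))
  g3 <- group_slices(d3, pql_grouping("Visit", "surname"))
  expect_identical(length(g3$slices[["group:Smith"]]$instances), 5L)
  expect_identical(length(g3$slices[["group:Jones"]]$instances), 2L)

  # a slice lacking the attribute stays a singleton group
  s4 <- quick_slice("N", inst("Visit", 0, 50), inst("Diagnose", 100, 150))
  g4 <- group_slices(quick_dataset(s4, mk("A", "Smith")),
                     pql_grouping("Visit", "surname"))
  expect_setequal(slice_ids(g4), c("group:Smith", "N"))
})

test_that("after grouping, intervals can span the original slice boundaries", {
  # the same patient appears twice; the visit-to-visit interval only exists
  # once the two transactions are merged
  s1 <- quick_slice("A",
    inst("Visit", hm(8), hm(8, 30), surname = "Smith"))
  s2 <- quick_slice("B",
    inst("Visit", hm(20), hm(20, 30), surname = "Smith"))
  d <- quick_dataset(s1, s2)
  q <- pql_query(
    grouping = pql_grouping("Visit", "surname"),
    intervals = list(pql_interval("readmit", "Visit", "Visit")))
  r <- apply_query(d, q)
  expect_identical(n_slices(r$dataset), 1L)
  expect_true(hm(12) %in% r$intervals$readmit[["group:Smith"]])
})
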