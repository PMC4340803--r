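# Hand-built fixtures: a small clinic model and quick slice/dataset builders.
# All fixtures are constructed in code at test time.

toy_model <- function() {
  medmod_model(
    name = "clinic",
    enumerations = list(ward = c("A", "B")),
    activities = list(
      medmod_activity("Visit",
                      list(medmod_attribute("age", "Integer"),
                           medmod_attribute("surname", "String")),
                      master = TRUE),
      medmod_activity("Stay",
                      list(medmod_attribute("total_expenses", "Real"),
                           medmod_attribute("unit", "ward"))),
      medmod_activity("Diagnose",
                      list(medmod_attribute("diagnosis", "String"),
                           medmod_attribute("when", "DateTime"))),
      medmod_activity("Procedure",
                      list(medmod_attribute("code", "String"),
                           medmod_attribute("cost", "Real"),
                           medmod_attribute("when", "DateTime"))),
      medmod_activity("Discharge")),
    edges = list(
      medmod_edge("follows", "Visit", "Stay"),
      medmod_edge("composition", "Stay", "Diagnose", cardinality = "*"),
      medmod_edge("composition", "Stay", "Procedure", cardinality = "*"),
      medmod_edge("interruption", "Stay", "Discharge")))
}

# ergonomic instance spec: inst("Diagnose", 100, diagnosis = "Flu")
inst <- function(activity, start, end = start + 10, ..., caused_by = NULL,
                 id = NULL) {
  attrs <- list(...)
  medmod_instance(if (is.null(id)) paste0("i", start, activity) else id,
                  activity, start, end, attributes = attrs,
                  caused_by = caused_by)
}

# a slice whose instance ids are made unique within the slice
quick_slice <- function(slice_id, ...) {
  instances <- list(...)
  for (k in seq_along(instances)) {
    instances[[k]]$instance_id <- sprintf("%s-%02d", slice_id, k)
  }
  medmod_slice(slice_id, instances)
}

quick_dataset <- function(..., model = toy_model()) {
  medmod_dataset(model, list(...))
}

# one fully conformant transaction of the clinic model, rooted at t0
conformant_toy_slice <- function(slice_id, t0 = 0) {
  ids <- function(k) sprintf("%s-%02d", slice_id, k)
  medmod_slice(slice_id, list(
    medmod_instance(ids(1), "Visit", t0, t0 + 100,
                    list(age = 30, surname = "Smith")),
    medmod_instance(ids(2), "Stay", t0 + 200, t0 + 2000,
                    list(total_expenses = 900, unit = "A"),
                    caused_by = list(instance = ids(1), kind = "follows")),
    medmod_instance(ids(3), "Diagnose", t0 + 300, t0 + 400,
                    list(diagnosis = "Flu", when = t0 + 350),
                    caused_by = list(instance = ids(2),
                                     kind = "composition")),
    medmod_instance(ids(4), "Procedure", t0 + 500, t0 + 700,
                    list(code = "XR", cost = 80, when = t0 + 600),
                    caused_by = list(instance = ids(2),
                                     kind = "composition")),
    medmod_instance(ids(5), "Discharge", t0 + 1500, t0 + 1600,
                    caused_by = list(instance = ids(2),
                                     kind = "interruption"))))
}

# structural normal form for dataset equality checks
normalize_dataset <- function(d) {
  lapply(d$slices, function(s) {
    lapply(s$instances, function(i)
      list(id = i$instance_id, activity = i$activity, slice = i$slice_id,
           start = i$start, end = i$end,
           attrs = if (length(i$attrs)) i$attrs[order(names(i$attrs))]
                   else list(),
           caused_by = i$caused_by))
  })
}

expect_same_dataset <- function(a, b) {
  expect_identical(slice_ids(a), slice_ids(b))
  expect_equal(normalize_dataset(a), normalize_dataset(b))
}
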