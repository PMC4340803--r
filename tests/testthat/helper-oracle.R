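# Brute-force reference implementations of the filtering operations, written
# as explicit set comprehensions over slices, independent of the engine's
# early-exit scan. They return sorted slice-id sets.

oracle_term <- function(x, op, const) {
  if (is.null(x) || !length(x)) return(FALSE)
  x <- x[!is.na(x)]
  if (!length(x)) return(FALSE)
  hits <- switch(op,
                 "="  = x == const, "!=" = x != const,
                 ">"  = x > const,  "<"  = x < const,
                 ">=" = x >= const, "<=" = x <= const,
                 "contains"    = grepl(const, x, fixed = TRUE),
                 "begins_with" = substr(x, 1, nchar(const)) == const,
                 "ends_with"   = substr(x, nchar(x) - nchar(const) + 1,
                                        nchar(x)) == const)
  any(hits)
}

oracle_instance_value <- function(i, cond, slice) {
  if (identical(cond$attribute, "count")) {
    sum(vapply(slice$instances, function(j) j$activity == cond$activity,
               logical(1)))
  } else {
    v <- i$attrs[[cond$attribute]]
    # DateTime constants may arrive as ISO strings; normalize like a user
    v
  }
}

oracle_comparison <- function(dataset, cond) {
  const1 <- cond$value
  const2 <- cond$value2
  ty <- tryCatch(medmod:::resolve_attr_type(dataset$model, cond$activity,
                                            cond$attribute,
                                            medmod:::dataset_derived(dataset)),
                 error = function(e) NULL)
  if (identical(ty, "DateTime")) {
    if (is.character(const1)) const1 <- medmod:::parse_time(const1)
    if (is.character(const2)) const2 <- medmod:::parse_time(const2)
  }
  ids <- Filter(function(sid) {
    s <- dataset$slices[[sid]]
    any(vapply(s$instances, function(i) {
      if (i$activity != cond$activity) return(FALSE)
      x <- oracle_instance_value(i, cond, s)
      r1 <- oracle_term(x, cond$op, const1)
      if (is.null(cond$combine)) return(r1)
      r2 <- oracle_term(x, cond$op2, const2)
      if (cond$combine == "AND") r1 && r2 else r1 || r2
    }, logical(1)))
  }, names(dataset$slices))
  sort(unlist(ids, use.names = FALSE) %||% character(0))
}

oracle_slice_aggregate <- function(dataset, cond) {
  ids <- Filter(function(sid) {
    s <- dataset$slices[[sid]]
    mine <- Filter(function(i) i$activity == cond$activity, s$instances)
    if (!length(mine)) return(FALSE)
    agg <- if (cond$fun == "Count") {
      length(mine)
    } else {
      vals <- unlist(lapply(mine, function(i) i$attrs[[cond$attribute]]))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(FALSE)
      if (cond$fun == "Sum") sum(vals) else mean(vals)
    }
    oracle_term(agg, cond$op, cond$value)
  }, names(dataset$slices))
  sort(unlist(ids, use.names = FALSE) %||% character(0))
}

oracle_partition <- function(dataset, cond) {
  recs <- lapply(names(dataset$slices), function(sid) {
    s <- dataset$slices[[sid]]
    vals <- unlist(lapply(s$instances, function(i)
      if (i$activity == cond$activity) i$attrs[[cond$attribute]] else NULL))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NULL)
    list(sid = sid,
         v = if (cond$direction == "Top") max(vals) else min(vals))
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) return(character(0))
  sid <- vapply(recs, `[[`, character(1), "sid")
  v <- vapply(recs, `[[`, numeric(1), "v")
  ord <- if (cond$direction == "Top") order(-v, sid) else order(v, sid)
  sort(sid[ord][seq_len(min(cond$k, length(sid)))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random condition generators over the demo model's attribute catalog
random_comparison <- function() {
  pick <- sample(6, 1)
  surnames <- c("Smith", "Jones", "Berzins", "Ozols", "Kalnins", "Liepa",
                "Martin", "Garcia", "Novak", "Petrov", "Andersen", "Keller",
                "Nobody")
  diagnoses <- c("Chickenpox", "Pneumonia", "Stroke", "Influenza",
                 "Appendicitis", "Fracture")
  spec <- switch(pick,
    list(a = "Patient enters the hospital", at = "age",
         ops = c("=", "!=", ">", "<", ">=", "<="),
         val = function() sample(1:95, 1)),
    list(a = "Patient enters the hospital", at = "surname",
         ops = c("=", "!=", "contains", "begins_with", "ends_with"),
         val = function() {
       s <- sample(surnames, 1)
       if (stats::runif(1) < 0.3) substr(s, 1, 2) else s
    }),
    list(a = "Doctor sets diagnosis", at = "diagnosis", ops = c("=", "!="),
         val = function() sample(diagnoses, 1)),
    list(a = "Procedure is executed", at = "cost",
         ops = c("=", "!=", ">", "<", ">=", "<="),
         val = function() sample(20:300, 1)),
    list(a = "Clinical process in ward", at = "total_expenses",
         ops = c(">", "<", ">=", "<="),
         val = function() sample(200:8000, 1)),
    list(a = "Doctor assigns procedure", at = "procedure_code",
         ops = c("=", "!="),
         val = function() sample(c("XR", "CT", "US", "LAB", "ECG"), 1)))
  two <- stats::runif(1) < 0.4
  pql_comparison(spec$a, spec$at, sample(spec$ops, 1), spec$val(),
                 combine = if (two) sample(c("AND", "OR"), 1),
                 op2 = if (two) sample(spec$ops, 1),
                 value2 = if (two) spec$val())
}

random_aggregate <- function() {
  pick <- sample(4, 1)
  switch(pick,
    pql_aggregate("Procedure is executed", sample(c("Sum", "Average"), 1),
                  sample(c(">", "<", ">=", "<="), 1), sample(50:600, 1),
                  attribute = "cost"),
    pql_aggregate("Clinical process in ward", "Average",
                  sample(c(">", "<"), 1), sample(200:8000, 1),
                  attribute = "total_expenses"),
    pql_aggregate("Doctor sets diagnosis", "Count",
                  sample(c("=", ">", "<", ">=", "<="), 1), sample(0:4, 1)),
    pql_aggregate("Doctor assigns procedure", "Count",
                  sample(c(">", ">="), 1), sample(1:4, 1)))
}

random_partition <- function() {
  pick <- sample(3, 1)
  switch(pick,
    pql_partition("Clinical process in ward", "total_expenses",
                  sample(c("Top", "Bottom"), 1), sample(1:10, 1)),
    pql_partition("Procedure is executed", "cost",
                  sample(c("Top", "Bottom"), 1), sample(1:10, 1)),
    pql_partition("Patient enters the hospital", "age",
                  sample(c("Top", "Bottom"), 1), sample(1:10, 1)))
}
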