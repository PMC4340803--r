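# The PQL evaluation engine.
#
# All filtering operations follow the same linear-time discipline as the
# reference evaluation strategy: walk the slices, inspect instances, include
# whole slices. Every operation instruments the number of instance
# inspections it performed and exposes it via attr(result, "inspections"),
# which apply_query() accumulates into the result's inspection_count — the
# quantity the O(n) / k*n cost contract is stated about.

keep_slices <- function(dataset, keep, inspections) {
  out <- dataset
  out$slices <- dataset$slices[keep]
  attr(out, "inspections") <- inspections
  out
}

#' Instance inspections performed by the last filtering operation
#'
#' @param x a dataset returned by one of the `evaluate_*` filters.
#' @return integer count, or `NA` if `x` carries no instrumentation.
#' @export
inspections <- function(x) {
  v <- attr(x, "inspections")
  if (is.null(v)) NA_integer_ else v
}

#' Apply a comparison condition to a dataset
#'
#' Returns the sub-dataset of whole slices that contain at least one
#' instance of the condition's activity satisfying the (possibly two-term)
#' comparison. Evaluation walks each slice and stops inspecting it at the
#' first matching instance, so at most `n` instances are inspected in total,
#' where `n` is the number of instances in the dataset.
#'
#' @param dataset a `medmod_dataset`.
#' @param cond a [pql_comparison()].
#' @return the filtered dataset, with the inspection count attached (see
#'   [inspections()]).
#' @export
evaluate_comparison <- function(dataset, cond) {
  stopifnot(inherits(cond, "pql_comparison"))
  cond <- resolve_comparison(dataset$model, cond,
                             derived = dataset_derived(dataset))
  insp <- 0L
  keep <- logical(length(dataset$slices))
  for (si in seq_along(dataset$slices)) {
    s <- dataset$slices[[si]]
    cnt <- NULL
    if (identical(cond$type, "count")) {
      cnt <- sum(vapply(s$instances, function(i) i$activity == cond$activity,
                        logical(1)))
    }
    for (inst in s$instances) {
      insp <- insp + 1L
      if (instance_matches(inst, cond, count_value = cnt)) {
        keep[si] <- TRUE
        break
      }
    }
  }
  keep_slices(dataset, keep, insp)
}

#' Apply a per-slice aggregate condition to a dataset
#'
#' Computes `Sum`/`Average` of an attribute (or `Count` of instances) of one
#' activity within each slice and keeps the slices whose aggregate satisfies
#' the comparison. Slices with no instance of the activity always fail;
#' slices with instances but no attribute values fail Sum/Average. One pass
#' over the instances, so at most `n` inspections.
#'
#' @param dataset a `medmod_dataset`.
#' @param cond a [pql_aggregate()].
#' @return the filtered dataset with inspection count attached.
#' @export
evaluate_slice_aggregate <- function(dataset, cond) {
  stopifnot(inherits(cond, "pql_aggregate"))
  cond <- resolve_aggregate(dataset$model, cond,
                            derived = dataset_derived(dataset))
  insp <- 0L
  keep <- logical(length(dataset$slices))
  for (si in seq_along(dataset$slices)) {
    s <- dataset$slices[[si]]
    count <- 0L
    vals <- numeric(0)
    for (inst in s$instances) {
      insp <- insp + 1L
      if (inst$activity != cond$activity) next
      count <- count + 1L
      if (cond$fun != "Count") {
        v <- inst$attrs[[cond$attribute]]
        if (!is.null(v)) vals <- c(vals, v[!is.na(v)])
      }
    }
    if (count == 0L) next  # no instances of the filtered type: slice fails
    agg <- switch(cond$fun,
                  Count   = count,
                  Sum     = if (length(vals)) sum(vals) else NA_real_,
                  Average = if (length(vals)) mean(vals) else NA_real_)
    if (is.na(agg)) next   # zero valued instances: Sum/Average fail
    keep[si] <- compare_values(agg, cond$op, cond$value)
  }
  keep_slices(dataset, keep, insp)
}

#' Apply a Top/Bottom-k partitioning condition to a dataset
#'
#' Ranks slices by the extreme value (max for `Top`, min for `Bottom`) of an
#' attribute over their instances of one activity; ties break by ascending
#' slice id; the first `k` whole slices are returned. Slices with no valued
#' instance of the activity are unranked and never returned. The scan
#' inspects each instance once, well within the `k * n` inspection bound of
#' the evaluation strategy.
#'
#' @param dataset a `medmod_dataset`.
#' @param cond a [pql_partition()].
#' @param k_max upper bound on admissible `k` (top-k queries are meant for a
#'   few extremes; the bound keeps evaluation linear).
#' @return the filtered dataset with inspection count attached.
#' @export
evaluate_partition <- function(dataset, cond, k_max = 100L) {
  stopifnot(inherits(cond, "pql_partition"))
  cond <- resolve_partition(dataset$model, cond, k_max,
                            derived = dataset_derived(dataset))
  insp <- 0L
  extreme <- rep(NA_real_, length(dataset$slices))
  for (si in seq_along(dataset$slices)) {
    s <- dataset$slices[[si]]
    best <- NA_real_
    for (inst in s$instances) {
      insp <- insp + 1L
      if (inst$activity != cond$activity) next
      v <- inst$attrs[[cond$attribute]]
      if (is.null(v)) next
      v <- v[!is.na(v)]
      if (!length(v)) next
      v <- if (cond$direction == "Top") max(v) else min(v)
      if (is.na(best)) best <- v
      else best <- if (cond$direction == "Top") max(best, v) else min(best, v)
    }
    extreme[si] <- best
  }
  ranked <- which(!is.na(extreme))
  ids <- names(dataset$slices)[ranked]
  vals <- extreme[ranked]
  ord <- if (cond$direction == "Top") {
    order(-vals, ids, method = "radix")
  } else {
    order(vals, ids, method = "radix")
  }
  take <- ranked[ord][seq_len(min(cond$k, length(ranked)))]
  keep <- logical(length(dataset$slices))
  keep[take] <- TRUE
  keep_slices(dataset, keep, insp)
}

#' Single-number retrieval over a dataset
#'
#' `Count`, `Sum` and `Average` over all instances of an activity in the
#' (filtered) dataset — the indicator-box numbers of the query diagram.
#' Instances with absent attribute values are excluded from Sum/Average.
#'
#' @param dataset a `medmod_dataset`.
#' @param activity activity name.
#' @param fun `"Count"`, `"Sum"` or `"Average"`.
#' @param attribute numeric attribute name, required for Sum/Average.
#' @return a number; `Sum` of nothing is 0, `Count` of nothing is 0,
#'   `Average` of zero valued instances is `NA` (undefined).
#' @export
retrieve_aggregate <- function(dataset, activity, fun, attribute = NULL) {
  if (!fun %in% c("Count", "Sum", "Average")) {
    abort_argument("fun must be Count, Sum or Average")
  }
  if (is.null(get_activity(dataset$model, activity))) {
    abort_resolution(sprintf("unknown activity '%s'", activity))
  }
  if (fun == "Count") {
    return(sum(vapply(dataset$slices, function(s)
      sum(vapply(s$instances, function(i) i$activity == activity,
                 logical(1))), numeric(1))))
  }
  if (is.null(attribute)) abort_argument(sprintf("%s requires an attribute", fun))
  type <- resolve_attr_type(dataset$model, activity, attribute,
                            derived = dataset_derived(dataset))
  if (!type %in% c("Integer", "Real", "interval")) {
    abort_type(sprintf("%s requires a numeric attribute, '%s' is %s",
                       fun, attribute, type))
  }
  vals <- numeric(0)
  for (s in dataset$slices) {
    for (inst in s$instances) {
      if (inst$activity != activity) next
      v <- inst$attrs[[attribute]]
      if (!is.null(v)) vals <- c(vals, v[!is.na(v)])
    }
  }
  switch(fun,
         Sum     = sum(vals),
         Average = if (length(vals)) mean(vals) else NA_real_)
}

#' List all instances of an activity as a table
#'
#' One row per instance in the dataset, with the slice id column that lets
#' rows from several tables be matched to the same transaction.
#'
#' @param dataset a `medmod_dataset`.
#' @param activity activity name.
#' @return a data frame with columns `slice_id`, `instance_id`,
#'   `start_time`, `end_time` (ISO-8601) and then the activity's declared
#'   attributes in model order; rows sorted by (start time, instance id).
#' @export
instance_table <- function(dataset, activity) {
  act <- get_activity(dataset$model, activity)
  if (is.null(act)) abort_resolution(sprintf("unknown activity '%s'", activity))
  attr_names <- vapply(act$attributes, `[[`, character(1), "name")
  attr_types <- vapply(act$attributes, `[[`, character(1), "type")
  insts <- list()
  for (s in dataset$slices) {
    for (inst in s$instances) {
      if (inst$activity == activity) insts[[length(insts) + 1L]] <- inst
    }
  }
  na_for <- function(type) {
    switch(type, Integer = NA_real_, Real = NA_real_, DateTime = NA_real_,
           Boolean = NA, String = NA_character_, NA_character_)
  }
  tab <- data.frame(
    slice_id = vapply(insts, `[[`, character(1), "slice_id"),
    instance_id = vapply(insts, `[[`, character(1), "instance_id"),
    start_time = format_time(vapply(insts, `[[`, numeric(1), "start")),
    end_time = format_time(vapply(insts, `[[`, numeric(1), "end")),
    stringsAsFactors = FALSE)
  for (j in seq_along(attr_names)) {
    an <- attr_names[j]
    ty <- attr_types[j]
    col <- vapply(insts, function(i) {
      v <- i$attrs[[an]]
      if (is.null(v) || !length(v)) na_for(ty) else v[[1]]
    }, na_for(ty))
    if (ty == "DateTime") col <- format_time(col)
    tab[[an]] <- if (length(insts)) col else na_for(ty)[0]
  }
  if (nrow(tab)) {
    starts <- vapply(insts, `[[`, numeric(1), "start")
    tab <- tab[order(starts, tab$instance_id, method = "radix"), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Probability that one condition implies another
#'
#' The manual association-rule number: among the slices matching condition
#' `condA`, the fraction that also match `condB` — i.e. "if a patient has
#' Pneumonia, the probability that they also have Stroke". Computed as
#' `|slices(A and B)| / |slices(A)|` by composing [evaluate_comparison()].
#'
#' @param dataset a `medmod_dataset`.
#' @param condA,condB [pql_comparison()] conditions.
#' @return a number in `[0, 1]`, or `NA` when no slice matches `condA`.
#' @export
implication_probability <- function(dataset, condA, condB) {
  dA <- evaluate_comparison(dataset, condA)
  nA <- n_slices(dA)
  if (nA == 0L) return(NA_real_)
  nAB <- n_slices(evaluate_comparison(dA, condB))
  nAB / nA
}

#' Evaluate a complete query against a dataset
#'
#' Evaluation order, matching the interactive semantics:
#' \enumerate{
#'   \item interval definitions are computed per slice and attached to the
#'     slice's master instance as derived multi-valued attributes, so
#'     subsequent conditions may reference interval names;
#'   \item comparison and per-slice aggregate conditions are applied
#'     sequentially (each filters the previous result — slice-level AND);
#'   \item every partitioning condition is evaluated on that result and the
#'     partition outputs are intersected;
#'   \item the optional grouping merges slices of the filtered dataset, and
#'     intervals are recomputed on the group-slices (they may now span a
#'     patient's multiple appearances);
#'   \item retrieval requests and the default per-activity instance counts
#'     are computed on the final dataset.
#' }
#'
#' @param dataset a `medmod_dataset`.
#' @param query a [pql_query()].
#' @param k_max bound on partition `k`, passed to [evaluate_partition()].
#' @return a `pql_result` with fields `dataset` (the filtered/grouped
#'   dataset), `counts` (named per-activity instance counts), `aggregates`
#'   (list of evaluated sum/average/count requests), `tables` (named list of
#'   instance tables), `intervals` (per-slice interval values by name) and
#'   `inspection_count` (total instance inspections of the filtering stage).
#' @export
apply_query <- function(dataset, query, k_max = 100L) {
  stopifnot(inherits(query, "pql_query"))
  d <- attach_intervals(dataset, query$intervals)
  total_insp <- 0L

  for (cond in query$conditions) {
    d <- if (inherits(cond, "pql_comparison")) {
      evaluate_comparison(d, cond)
    } else if (inherits(cond, "pql_aggregate")) {
      evaluate_slice_aggregate(d, cond)
    } else {
      abort_argument("conditions must be pql_comparison or pql_aggregate")
    }
    total_insp <- total_insp + inspections(d)
  }

  if (length(query$partitions)) {
    keep_ids <- NULL
    for (p in query$partitions) {
      dp <- evaluate_partition(d, p, k_max = k_max)
      total_insp <- total_insp + inspections(dp)
      ids <- slice_ids(dp)
      keep_ids <- if (is.null(keep_ids)) ids else intersect(keep_ids, ids)
    }
    d$slices <- d$slices[names(d$slices) %in% keep_ids]
  }

  if (!is.null(query$grouping)) {
    d <- group_slices(d, query$grouping)
    if (length(query$intervals)) d <- attach_intervals(d, query$intervals)
  }

  interval_values <- list()
  for (idef in query$intervals) {
    interval_values[[idef$name]] <- lapply(d$slices, function(s)
      slice_interval_values(s, idef$name, dataset$model))
  }

  counts <- vapply(activity_names(d$model), function(a)
    sum(vapply(d$slices, function(s)
      sum(vapply(s$instances, function(i) i$activity == a, logical(1))),
      numeric(1))), numeric(1))

  aggregates <- list()
  tables <- list()
  for (r in query$retrievals) {
    if (r$type == "table") {
      tables[[r$activity]] <- instance_table(d, r$activity)
    } else {
      fun <- c(count = "Count", sum = "Sum", average = "Average")[[r$type]]
      aggregates[[length(aggregates) + 1L]] <- list(
        type = r$type, activity = r$activity, attribute = r$attribute,
        value = retrieve_aggregate(d, r$activity, fun, r$attribute))
    }
  }

  structure(list(dataset = d,
                 counts = counts,
                 aggregates = aggregates,
                 tables = tables,
                 intervals = interval_values,
                 inspection_count = total_insp),
            class = "pql_result")
}

#' @export
print.pql_result <- function(x, ...) {
  cat(sprintf("PQL result: %d slices, %d instances (inspections: %d)\n",
              n_slices(x$dataset), n_instances(x$dataset),
              x$inspection_count))
  nz <- x$counts[x$counts > 0]
  for (a in names(nz)) cat(sprintf("  %-45s %d\n", a, as.integer(nz[[a]])))
  for (ag in x$aggregates) {
    cat(sprintf("  %s(%s%s) = %s\n", ag$type, ag$activity,
                if (is.null(ag$attribute)) "" else paste0(".", ag$attribute),
                format(ag$value, digits = 6)))
  }
  invisible(x)
}
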