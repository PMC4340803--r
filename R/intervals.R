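# Time intervals and slice grouping.
#
# An interval is a derived, possibly multi-valued attribute of a slice: the
# elapsed seconds between instances of a start activity and an end activity.
# Values are attached to the slice's master instance(s) so that interval
# names can be used in filtering conditions exactly like attributes.

dataset_derived <- function(dataset) {
  d <- dataset$derived
  if (is.null(d)) character(0) else d
}

# Timestamp of an instance for interval purposes: a declared DateTime
# attribute if given, else the intrinsic start time.
endpoint_time <- function(inst, attribute) {
  if (is.null(attribute)) return(inst$start)
  v <- inst$attrs[[attribute]]
  if (is.null(v) || !length(v) || is.na(v[[1]])) NA_real_ else v[[1]]
}

check_endpoint <- function(model, activity, attribute, what) {
  if (is.null(get_activity(model, activity))) {
    abort_resolution(sprintf("unknown %s activity '%s'", what, activity))
  }
  if (!is.null(attribute)) {
    at <- get_attribute(model, activity, attribute)
    if (is.null(at)) {
      abort_resolution(sprintf("unknown attribute '%s' on activity '%s'",
                               attribute, activity))
    }
    if (at$type != "DateTime") {
      abort_type(sprintf("interval endpoint attribute '%s' must be DateTime, is %s",
                         attribute, at$type))
    }
  }
}

#' Compute the values of a time interval within one slice
#'
#' Collects the start instances (of `start_activity`) and end instances (of
#' `end_activity`) of the slice and pairs them by time order: each start is
#' matched to the earliest not-yet-paired end at or after it, so durations
#' are never negative. With a pairing condition, the match additionally
#' requires equality of the two named attributes (e.g. the same procedure
#' code on assignment and execution) and pairing runs within each key class.
#' Multiple values arise naturally when the slice holds several start/end
#' instances.
#'
#' @param slice a `medmod_slice`.
#' @param idef a [pql_interval()] definition.
#' @param model the `medmod_model` the slice conforms to.
#' @return numeric vector of durations in seconds (possibly empty).
#' @export
compute_intervals <- function(slice, idef, model) {
  check_endpoint(model, idef$start_activity, idef$start_attribute, "start")
  check_endpoint(model, idef$end_activity, idef$end_attribute, "end")

  starts <- list()
  ends <- list()
  for (inst in slice$instances) {
    if (inst$activity == idef$start_activity) {
      t <- endpoint_time(inst, idef$start_attribute)
      if (!is.na(t)) starts[[length(starts) + 1L]] <- list(inst = inst, t = t)
    }
    if (inst$activity == idef$end_activity) {
      t <- endpoint_time(inst, idef$end_attribute)
      if (!is.na(t)) ends[[length(ends) + 1L]] <- list(inst = inst, t = t)
    }
  }
  if (!length(starts) || !length(ends)) return(numeric(0))

  key_of <- function(rec, attribute) {
    v <- rec$inst$attrs[[attribute]]
    if (is.null(v) || !length(v) || is.na(v[[1]])) NA_character_
    else as.character(v[[1]])
  }
  if (!is.null(idef$pairing)) {
    skeys <- vapply(starts, key_of, character(1), idef$pairing[[1]])
    ekeys <- vapply(ends, key_of, character(1), idef$pairing[[2]])
    starts <- starts[!is.na(skeys)]
    ends <- ends[!is.na(ekeys)]
    skeys <- skeys[!is.na(skeys)]
    ekeys <- ekeys[!is.na(ekeys)]
  } else {
    skeys <- rep("", length(starts))
    ekeys <- rep("", length(ends))
  }

  durations <- numeric(0)
  for (key in unique(skeys)) {
    ss <- starts[skeys == key]
    ee <- ends[ekeys == key]
    if (!length(ss) || !length(ee)) next
    ss <- ss[order(vapply(ss, `[[`, numeric(1), "t"))]
    ee <- ee[order(vapply(ee, `[[`, numeric(1), "t"))]
    used <- logical(length(ee))
    for (srec in ss) {
      for (j in seq_along(ee)) {
        if (used[j]) next
        erec <- ee[[j]]
        if (erec$t < srec$t) next
        if (identical(erec$inst$instance_id, srec$inst$instance_id)) next
        used[j] <- TRUE
        durations <- c(durations, erec$t - srec$t)
        break
      }
    }
  }
  durations
}

# Compute every interval of a query on every slice and attach the value
# vectors to the master instance(s) as derived attributes; register the
# interval names on the dataset so conditions can resolve them.
attach_intervals <- function(dataset, intervals) {
  if (!length(intervals)) return(dataset)
  master <- master_activity(dataset$model)
  out <- dataset
  for (idef in intervals) {
    for (sid in names(out$slices)) {
      vals <- compute_intervals(out$slices[[sid]], idef, out$model)
      for (k in seq_along(out$slices[[sid]]$instances)) {
        if (out$slices[[sid]]$instances[[k]]$activity == master) {
          out$slices[[sid]]$instances[[k]]$attrs[[idef$name]] <- vals
        }
      }
    }
    out$derived <- union(dataset_derived(out), idef$name)
  }
  out
}

# Interval values of one slice, read back from the master instance.
slice_interval_values <- function(slice, name, model) {
  master <- master_activity(model)
  for (inst in slice$instances) {
    if (inst$activity == master) {
      v <- inst$attrs[[name]]
      return(if (is.null(v)) numeric(0) else v)
    }
  }
  numeric(0)
}

#' Merge slices that share an attribute value
#'
#' Slices whose instances of `activity` share the same value of `attribute`
#' (e.g. the patient's surname across multiple hospital stays) are merged
#' into one group-slice whose id is derived from the key. A slice holding
#' several different key values is assigned to the key of its earliest keyed
#' instance, preserving slice disjointness; slices with no keyed instance
#' stay singleton groups under their own id. Intervals computed after
#' grouping may span the original slice boundaries.
#'
#' @param dataset a `medmod_dataset`.
#' @param g a [pql_grouping()] definition.
#' @return a grouped `medmod_dataset` (flagged with `$grouped = TRUE`; a
#'   group-slice can hold several master instances, so grouped datasets are
#'   not meant to be re-validated with [validate_trace()]).
#' @export
group_slices <- function(dataset, g) {
  stopifnot(inherits(g, "pql_grouping"))
  resolve_attr_type(dataset$model, g$activity, g$attribute,
                    derived = dataset_derived(dataset))
  keys <- vapply(dataset$slices, function(s) {
    best_t <- Inf
    best_id <- ""
    best_key <- NA_character_
    for (inst in s$instances) {
      if (inst$activity != g$activity) next
      v <- inst$attrs[[g$attribute]]
      if (is.null(v) || !length(v) || is.na(v[[1]])) next
      if (inst$start < best_t ||
          (inst$start == best_t && inst$instance_id < best_id)) {
        best_t <- inst$start
        best_id <- inst$instance_id
        best_key <- as.character(v[[1]])
      }
    }
    best_key
  }, character(1))

  new_slices <- list()
  for (si in seq_along(dataset$slices)) {
    if (is.na(keys[si])) {
      s <- dataset$slices[[si]]
      new_slices[[length(new_slices) + 1L]] <- s
    }
  }
  for (key in unique(keys[!is.na(keys)])) {
    members <- dataset$slices[which(!is.na(keys) & keys == key)]
    gid <- paste0("group:", key)
    insts <- do.call(c, lapply(members, `[[`, "instances"))
    new_slices[[length(new_slices) + 1L]] <- medmod_slice(gid, insts)
  }
  out <- medmod_dataset(dataset$model, new_slices)
  out$derived <- dataset$derived
  out$grouped <- TRUE
  out
}
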