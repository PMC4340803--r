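# Runtime side of the language: instances, slices, datasets.
#
# An instance is one concrete execution of an activity. A slice is the set of
# all instances of one transaction, rooted at one master-activity instance;
# slices never share instances. A dataset is a set of disjoint slices plus a
# reference to the model they conform to — the unit every query filters.
#
# Internal encoding: timestamps as numeric epoch seconds; attribute values as
# typed R scalars (Integer/Real/DateTime -> numeric, String/enumeration ->
# character, Boolean -> logical); missing values simply absent from the
# attribute map, never defaulted.

#' Create a run-time activity instance
#'
#' @param instance_id identifier, unique within the trace.
#' @param activity name of the activity this instance executes.
#' @param start_time,end_time ISO-8601 strings or epoch seconds; `end_time`
#'   may be `NA` for a suspended/open instance.
#' @param attributes named list of attribute values (absent = missing).
#' @param caused_by `NULL` for the master instance, otherwise
#'   `list(instance = <predecessor instance_id>, kind = <edge kind>)` naming
#'   the flow/composition/extension occurrence that created this instance.
#' @param slice_id usually assigned by [medmod_slice()].
#' @return a `medmod_instance` list.
#' @export
medmod_instance <- function(instance_id, activity, start_time,
                            end_time = NA, attributes = list(),
                            caused_by = NULL, slice_id = NA_character_) {
  if (is.character(start_time)) start_time <- parse_time(start_time)
  if (is.character(end_time)) end_time <- parse_time(end_time)
  if (length(end_time) == 0L || is.null(end_time)) end_time <- NA_real_
  if (!is.na(end_time) && end_time < start_time) {
    abort_structural(sprintf(
      "instance '%s': end_time precedes start_time", instance_id))
  }
  if (!is.null(caused_by) &&
      (is.null(caused_by$instance) || is.null(caused_by$kind))) {
    abort_structural(sprintf(
      "instance '%s': caused_by needs fields 'instance' and 'kind'",
      instance_id))
  }
  structure(list(instance_id = as.character(instance_id),
                 activity = activity,
                 slice_id = as.character(slice_id),
                 start = as.numeric(start_time),
                 end = as.numeric(end_time),
                 attrs = attributes,
                 caused_by = caused_by),
            class = "medmod_instance")
}

#' Create a slice (one transaction)
#'
#' @param slice_id identifier, unique within the dataset.
#' @param instances list of [medmod_instance()]; their `slice_id` fields are
#'   overwritten with `slice_id`.
#' @return a `medmod_slice` list.
#' @export
medmod_slice <- function(slice_id, instances = list()) {
  instances <- lapply(instances, function(i) {
    i$slice_id <- as.character(slice_id)
    i
  })
  structure(list(slice_id = as.character(slice_id), instances = instances),
            class = "medmod_slice")
}

#' Create a dataset of disjoint slices
#'
#' @param model the [medmod_model()] the trace conforms to.
#' @param slices list of [medmod_slice()] objects.
#' @return a `medmod_dataset`; slices are stored in a named list keyed and
#'   ordered by `slice_id` (ascending, the canonical tie-break order).
#' @export
medmod_dataset <- function(model, slices = list()) {
  ids <- vapply(slices, `[[`, character(1), "slice_id")
  if (anyDuplicated(ids)) {
    abort_structural(sprintf("duplicate slice_id: %s",
                             paste(unique(ids[duplicated(ids)]),
                                   collapse = ", ")))
  }
  slices <- slices[order(ids, method = "radix")]
  names(slices) <- sort(ids, method = "radix")
  structure(list(model = model, slices = slices), class = "medmod_dataset")
}

#' Number of instances in a dataset
#'
#' The size symbol of the linear-time evaluation contract: a single
#' comparison condition inspects at most this many instances.
#'
#' @param dataset a `medmod_dataset`.
#' @return integer instance count.
#' @export
n_instances <- function(dataset) {
  sum(vapply(dataset$slices, function(s) length(s$instances), integer(1)))
}

#' Number of slices in a dataset
#' @param dataset a `medmod_dataset`.
#' @return integer slice count.
#' @export
n_slices <- function(dataset) length(dataset$slices)

#' Slice identifiers of a dataset, ascending
#' @param dataset a `medmod_dataset`.
#' @return character vector of slice ids.
#' @export
slice_ids <- function(dataset) names(dataset$slices)

# Type-check one attribute value against a declared type. Returns NULL when
# fine, else a message.
check_value <- function(value, type, model) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(NULL)
  if (type %in% c("Integer", "Real", "DateTime")) {
    if (!is.numeric(value)) return(sprintf("expected %s, got %s", type,
                                           class(value)[1]))
    if (type == "Integer" && any(value != floor(value))) {
      return("expected Integer, got fractional value")
    }
    return(NULL)
  }
  if (type == "Boolean") {
    if (!is.logical(value)) return("expected Boolean")
    return(NULL)
  }
  if (type == "String") {
    if (!is.character(value)) return("expected String")
    return(NULL)
  }
  # enumeration
  lits <- model$enumerations[[type]]
  if (is.null(lits)) return(sprintf("unknown enumeration '%s'", type))
  if (!is.character(value) || !all(value %in% lits)) {
    return(sprintf("value not a literal of enumeration '%s'", type))
  }
  NULL
}

#' Check a trace for conformance against its model
#'
#' Validates the runtime semantics of every relation kind:
#' \describe{
#'   \item{T1}{slices are disjoint — no `instance_id` appears twice.}
#'   \item{T2}{each slice holds exactly one master instance, which has no
#'     `caused_by`; every other instance records its causal predecessor.}
#'   \item{T3}{each `caused_by` link corresponds to a model edge of the same
#'     kind with matching source/target activities.}
#'   \item{T4}{follows timing: a successor starts no earlier than its
#'     predecessor ends (a predecessor with an open end time yields a
#'     warning, not a violation).}
#'   \item{T5}{XOR: an instance is the follows-predecessor of at most one
#'     successor.}
#'   \item{T6}{composition cardinalities hold per aggregate instance.}
#'   \item{T7}{interruption: once an instance interrupts an aggregate
#'     instance, no component of that aggregate instance starts later than
#'     the interrupting instance's start.}
#'   \item{T8}{attribute values type-check and enumeration values are
#'     declared literals.}
#' }
#'
#' @param dataset a `medmod_dataset`.
#' @param model defaults to `dataset$model`; must itself be valid.
#' @return data frame of violations (`rule`, `severity`, `element`,
#'   `message`); zero rows for a conformant trace.
#' @export
validate_trace <- function(dataset, model = dataset$model) {
  v <- list(empty_violations())
  acts <- activity_names(model)
  master <- master_activity(model)

  # T1 global instance-id disjointness
  all_ids <- unlist(lapply(dataset$slices, function(s)
    vapply(s$instances, `[[`, character(1), "instance_id")), use.names = FALSE)
  for (d in unique(all_ids[duplicated(all_ids)])) {
    v[[length(v) + 1L]] <- violation("T1", "error", d,
      sprintf("instance_id '%s' appears in more than one instance", d))
  }

  comp_edges <- Filter(function(e) e$kind == "composition", model$edges)

  for (s in dataset$slices) {
    idx <- stats::setNames(seq_along(s$instances),
                           vapply(s$instances, `[[`, character(1),
                                  "instance_id"))
    # resolve caused_by; dangling references are structural, not violations
    for (i in s$instances) {
      if (!i$activity %in% acts) {
        abort_resolution(sprintf(
          "instance '%s' references unknown activity '%s'",
          i$instance_id, i$activity))
      }
      if (!is.null(i$caused_by) && is.na(idx[i$caused_by$instance])) {
        abort_structural(sprintf(
          "instance '%s': caused_by references '%s', absent from slice '%s'",
          i$instance_id, i$caused_by$instance, s$slice_id))
      }
    }

    # T2 master shape
    masters <- Filter(function(i) i$activity == master, s$instances)
    if (length(masters) != 1L) {
      v[[length(v) + 1L]] <- violation("T2", "error", s$slice_id,
        sprintf("slice '%s' has %d master instances, expected 1",
                s$slice_id, length(masters)))
    }
    for (m in masters) {
      if (!is.null(m$caused_by)) {
        v[[length(v) + 1L]] <- violation("T2", "error", m$instance_id,
          sprintf("master instance '%s' must not have caused_by",
                  m$instance_id))
      }
    }
    for (i in s$instances) {
      if (i$activity != master && is.null(i$caused_by)) {
        v[[length(v) + 1L]] <- violation("T2", "error", i$instance_id,
          sprintf("non-master instance '%s' lacks caused_by", i$instance_id))
      }
    }

    follows_pred <- character(0)
    for (i in s$instances) {
      cb <- i$caused_by
      if (is.null(cb)) next
      pred <- s$instances[[idx[cb$instance]]]
      # T3 edge existence
      hit <- FALSE
      for (e in model$edges) {
        if (e$kind == cb$kind && e$source == pred$activity &&
            e$target == i$activity) { hit <- TRUE; break }
      }
      if (!hit) {
        v[[length(v) + 1L]] <- violation("T3", "error", i$instance_id,
          sprintf("no %s edge '%s' -> '%s' in the model for instance '%s'",
                  cb$kind, pred$activity, i$activity, i$instance_id))
      }
      # T4 follows timing
      if (cb$kind == "follows") {
        follows_pred <- c(follows_pred, pred$instance_id)
        if (is.na(pred$end)) {
          v[[length(v) + 1L]] <- violation("T4", "warning", i$instance_id,
            sprintf("follows-predecessor '%s' of '%s' has no end time",
                    pred$instance_id, i$instance_id))
        } else if (i$start < pred$end) {
          v[[length(v) + 1L]] <- violation("T4", "error", i$instance_id,
            sprintf("instance '%s' starts before its follows-predecessor '%s' ends",
                    i$instance_id, pred$instance_id))
        }
      }
    }
    # T5 XOR: at most one follows-successor per instance
    for (d in unique(follows_pred[duplicated(follows_pred)])) {
      v[[length(v) + 1L]] <- violation("T5", "error", d,
        sprintf("instance '%s' has more than one follows-successor", d))
    }

    # T6 / T7 per aggregate instance
    for (agg in s$instances) {
      kids <- Filter(function(i) !is.null(i$caused_by) &&
                       i$caused_by$kind == "composition" &&
                       i$caused_by$instance == agg$instance_id, s$instances)
      interrupters <- Filter(function(i) !is.null(i$caused_by) &&
                               i$caused_by$kind == "interruption" &&
                               i$caused_by$instance == agg$instance_id,
                             s$instances)
      my_edges <- Filter(function(e) e$source == agg$activity, comp_edges)
      if (length(my_edges)) {
        for (e in my_edges) {
          k <- sum(vapply(kids, function(i) i$activity == e$target,
                          logical(1)))
          bad <- switch(e$cardinality,
                        "1"    = k != 1L,
                        "0..1" = k > 1L,
                        "1..*" = k < 1L,
                        "*"    = FALSE)
          if (bad) {
            v[[length(v) + 1L]] <- violation("T6", "error", agg$instance_id,
              sprintf("aggregate instance '%s' has %d '%s' components, cardinality %s",
                      agg$instance_id, k, e$target, e$cardinality))
          }
        }
      }
      if (length(interrupters) && length(kids)) {
        t_int <- min(vapply(interrupters, `[[`, numeric(1), "start"))
        for (kid in kids) {
          if (!is.na(kid$start) && kid$start > t_int) {
            v[[length(v) + 1L]] <- violation("T7", "error", kid$instance_id,
              sprintf("component '%s' starts after aggregate '%s' was interrupted",
                      kid$instance_id, agg$instance_id))
          }
        }
      }
    }

    # T8 attribute typing
    for (i in s$instances) {
      if (!length(i$attrs)) next
      for (an in names(i$attrs)) {
        at <- get_attribute(model, i$activity, an)
        if (is.null(at)) {
          v[[length(v) + 1L]] <- violation("T8", "error", i$instance_id,
            sprintf("instance '%s' carries undeclared attribute '%s'",
                    i$instance_id, an))
          next
        }
        msg <- check_value(i$attrs[[an]], at$type, model)
        if (!is.null(msg)) {
          v[[length(v) + 1L]] <- violation("T8", "error", i$instance_id,
            sprintf("instance '%s', attribute '%s': %s", i$instance_id, an,
                    msg))
        }
      }
    }
  }
  do.call(rbind, v)
}

#' Select the slices of a time window
#'
#' The initial dataset of a query: all slices whose transaction was born in
#' the chosen time interval. Membership is keyed on the master instance's
#' start time with half-open `[window_start, window_end)` semantics, so
#' disjoint windows partition the slices. Slices are never split.
#'
#' @param dataset a `medmod_dataset`.
#' @param window_start,window_end ISO-8601 strings or epoch seconds;
#'   `window_start < window_end` required.
#' @return the sub-dataset of whole slices in the window.
#' @export
build_initial_dataset <- function(dataset, window_start, window_end) {
  if (is.character(window_start)) window_start <- parse_time(window_start)
  if (is.character(window_end)) window_end <- parse_time(window_end)
  if (is.na(window_start) || is.na(window_end) ||
      !(window_start < window_end)) {
    abort_argument("window_start must be strictly before window_end")
  }
  master <- master_activity(dataset$model)
  keep <- vapply(dataset$slices, function(s) {
    for (i in s$instances) {
      if (i$activity == master) {
        return(!is.na(i$start) && i$start >= window_start &&
                 i$start < window_end)
      }
    }
    FALSE
  }, logical(1))
  out <- dataset
  out$slices <- dataset$slices[keep]
  out
}

#' @export
print.medmod_dataset <- function(x, ...) {
  cat(sprintf("MedMod dataset on model '%s': %d slices, %d instances\n",
              x$model$name, n_slices(x), n_instances(x)))
  invisible(x)
}
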