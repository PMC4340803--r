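# Readers and writers for the three wire dialects (model JSON, trace
# JSON/CSV, query JSON) and the results JSON. Schema documents for the
# dialects ship under inst/schemas/; since no JSON-Schema validator is
# available at run time, the readers enforce the same structural rules in
# code and report a JSON-pointer-style location on failure. Parsing is
# separate from semantic validation: a structurally sound file with, say, no
# master activity loads fine and fails validate_model() afterwards.
#
# All writers are deterministic — stable key order, fixed number formatting —
# so golden-file comparisons and byte-identity checks are exact.

json_read <- function(path, what) {
  if (!file.exists(path)) {
    abort_load(sprintf("%s file not found: %s", what, path),
               code = paste0(what, "_not_found"))
  }
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e) {
             abort_load(sprintf("malformed JSON in %s: %s", path,
                                conditionMessage(e)))
           })
}

need <- function(x, field, ptr) {
  if (is.null(x[[field]])) {
    abort_load(sprintf("missing required field at %s/%s", ptr, field))
  }
  x[[field]]
}

#' Read a process model from JSON
#'
#' @param path file path.
#' @return a `medmod_model`; run [validate_model()] for well-formedness.
#' @export
read_model <- function(path) {
  j <- json_read(path, "model")
  name <- need(j, "name", "")
  enums <- list()
  for (i in seq_along(j$enumerations)) {
    e <- j$enumerations[[i]]
    ptr <- sprintf("/enumerations/%d", i - 1L)
    enums[[need(e, "name", ptr)]] <-
      as.character(unlist(need(e, "literals", ptr)))
  }
  acts <- lapply(seq_along(j$activities), function(i) {
    a <- j$activities[[i]]
    ptr <- sprintf("/activities/%d", i - 1L)
    attrs <- lapply(seq_along(a$attributes), function(k) {
      at <- a$attributes[[k]]
      aptr <- sprintf("%s/attributes/%d", ptr, k - 1L)
      medmod_attribute(need(at, "name", aptr), need(at, "type", aptr))
    })
    medmod_activity(need(a, "name", ptr), attrs, master = isTRUE(a$master))
  })
  edges <- lapply(seq_along(j$edges), function(i) {
    e <- j$edges[[i]]
    ptr <- sprintf("/edges/%d", i - 1L)
    tryCatch(
      medmod_edge(need(e, "kind", ptr), need(e, "source", ptr),
                  need(e, "target", ptr),
                  cardinality = e$cardinality,
                  extension_point = e$extension_point),
      medmod_structural_error = function(err) {
        abort_load(sprintf("at %s: %s", ptr, conditionMessage(err)))
      })
  })
  medmod_model(name, activities = acts, edges = edges, enumerations = enums)
}

#' Write a process model to JSON
#'
#' `read_model()` of the written file reproduces the model exactly.
#'
#' @param model a `medmod_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  j <- list(
    name = model$name,
    enumerations = lapply(names(model$enumerations), function(n)
      list(name = n, literals = as.list(model$enumerations[[n]]))),
    activities = lapply(model$activities, function(a)
      list(name = a$name, master = isTRUE(a$master),
           attributes = lapply(a$attributes, function(at)
             list(name = at$name, type = at$type)))),
    edges = lapply(model$edges, function(e) {
      x <- list(kind = e$kind, source = e$source, target = e$target)
      if (!is.null(e$cardinality)) x$cardinality <- e$cardinality
      if (!is.null(e$extension_point)) x$extension_point <- e$extension_point
      x
    }))
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

# union of declared attributes in model order; shared names must agree on type
model_attr_columns <- function(model) {
  names_seen <- character(0)
  types <- character(0)
  for (a in model$activities) {
    for (at in a$attributes) {
      if (at$name %in% names_seen) {
        if (types[[match(at$name, names_seen)]] != at$type) {
          abort_structural(sprintf(
            "attribute '%s' is declared with two types; the flat CSV dialect needs one",
            at$name))
        }
      } else {
        names_seen <- c(names_seen, at$name)
        types <- c(types, at$type)
      }
    }
  }
  stats::setNames(types, names_seen)
}

attr_to_wire <- function(v, type) {
  if (is.null(v) || !length(v) || all(is.na(v))) return(NULL)
  if (type == "DateTime") format_time(v) else v
}

attr_from_wire <- function(v, type) {
  switch(type,
         Integer = as.numeric(v),
         Real = as.numeric(v),
         DateTime = if (is.character(v)) parse_time(v) else as.numeric(v),
         Boolean = as.logical(v),
         as.character(v))  # String and enumerations
}

#' Write a trace dataset to JSON or CSV
#'
#' The JSON dialect nests instances in slices; the flat CSV dialect (RFC
#' 4180) has columns `slice_id`, `instance_id`, `activity`, `start_time`,
#' `end_time`, `caused_by_id`, `caused_by_kind`, then one column per
#' declared attribute. The two forms round-trip losslessly.
#'
#' @param dataset a `medmod_dataset`.
#' @param path file path.
#' @param format `"json"` or `"csv"`; the default guesses from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_trace <- function(dataset, path,
                        format = if (grepl("\\.csv$", path)) "csv" else "json") {
  model <- dataset$model
  if (format == "json") {
    j <- list(
      model = model$name,
      slices = lapply(unname(dataset$slices), function(s)
        list(slice_id = s$slice_id,
             instances = lapply(s$instances, function(i) {
               act <- get_activity(model, i$activity)
               attrs <- list()
               for (at in act$attributes) {
                 w <- attr_to_wire(i$attrs[[at$name]], at$type)
                 if (!is.null(w)) attrs[[at$name]] <- w
               }
               x <- list(instance_id = i$instance_id, activity = i$activity,
                         start_time = format_time(i$start),
                         end_time = if (is.na(i$end)) NULL
                                    else format_time(i$end))
               if (!is.null(i$caused_by)) {
                 x$caused_by <- list(instance = i$caused_by$instance,
                                     kind = i$caused_by$kind)
               }
               x$attributes <- attrs
               x
             }))))
    writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), path)
    return(invisible(path))
  }
  if (format != "csv") abort_argument("format must be 'json' or 'csv'")
  cols <- model_attr_columns(model)
  rows <- list()
  for (s in unname(dataset$slices)) {
    for (i in s$instances) {
      act <- get_activity(model, i$activity)
      row <- c(slice_id = s$slice_id, instance_id = i$instance_id,
               activity = i$activity,
               start_time = format_time(i$start),
               end_time = if (is.na(i$end)) "" else format_time(i$end),
               caused_by_id = if (is.null(i$caused_by)) ""
                              else i$caused_by$instance,
               caused_by_kind = if (is.null(i$caused_by)) ""
                                else i$caused_by$kind)
      for (an in names(cols)) {
        declared <- !is.null(get_attribute(model, i$activity, an))
        w <- if (declared) attr_to_wire(i$attrs[[an]], cols[[an]]) else NULL
        row[[an]] <- if (is.null(w)) "" else as.character(w)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  header <- c("slice_id", "instance_id", "activity", "start_time",
              "end_time", "caused_by_id", "caused_by_kind", names(cols))
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!length(rows)) {
    tab <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(header)), header))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a trace dataset from JSON or CSV
#'
#' @param path file path.
#' @param model the `medmod_model` the trace conforms to (needed to type
#'   attribute values).
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return a `medmod_dataset` carrying `model`.
#' @export
read_trace <- function(path, model,
                       format = if (grepl("\\.csv$", path)) "csv" else "json") {
  acts <- activity_names(model)
  check_ids <- function(ids) {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      abort_load(sprintf("duplicate instance_id: %s",
                         paste(dup, collapse = ", ")))
    }
  }
  if (format == "json") {
    j <- json_read(path, "trace")
    slices <- lapply(seq_along(j$slices), function(si) {
      s <- j$slices[[si]]
      ptr <- sprintf("/slices/%d", si - 1L)
      sid <- need(s, "slice_id", ptr)
      insts <- lapply(seq_along(s$instances), function(ii) {
        i <- s$instances[[ii]]
        iptr <- sprintf("%s/instances/%d", ptr, ii - 1L)
        activity <- need(i, "activity", iptr)
        if (!activity %in% acts) {
          abort_load(sprintf("at %s: unknown activity '%s'", iptr, activity))
        }
        attrs <- list()
        for (an in names(i$attributes)) {
          at <- get_attribute(model, activity, an)
          ty <- if (is.null(at)) "String" else at$type
          attrs[[an]] <- attr_from_wire(unlist(i$attributes[[an]]), ty)
        }
        medmod_instance(need(i, "instance_id", iptr), activity,
                        start_time = need(i, "start_time", iptr),
                        end_time = if (is.null(i$end_time)) NA
                                   else i$end_time,
                        attributes = attrs,
                        caused_by = i$caused_by, slice_id = sid)
      })
      medmod_slice(sid, insts)
    })
    d <- medmod_dataset(model, slices)
  } else {
    if (format != "csv") abort_argument("format must be 'json' or 'csv'")
    if (!file.exists(path)) {
      abort_load(sprintf("trace file not found: %s", path),
                 code = "trace_not_found")
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
    cols <- model_attr_columns(model)
    bad <- setdiff(unique(tab$activity), acts)
    if (length(bad)) {
      abort_load(sprintf("unknown activity: %s", paste(bad, collapse = ", ")))
    }
    slices <- lapply(split(seq_len(nrow(tab)), tab$slice_id), function(ix) {
      rows <- tab[ix, , drop = FALSE]
      insts <- lapply(seq_len(nrow(rows)), function(r) {
        row <- rows[r, ]
        attrs <- list()
        for (an in names(cols)) {
          if (!an %in% names(row)) next
          v <- row[[an]]
          if (is.na(v) || !nzchar(v)) next
          if (is.null(get_attribute(model, row$activity, an))) next
          attrs[[an]] <- attr_from_wire(v, cols[[an]])
        }
        medmod_instance(
          row$instance_id, row$activity,
          start_time = row$start_time,
          end_time = if (!nzchar(row$end_time)) NA else row$end_time,
          attributes = attrs,
          caused_by = if (nzchar(row$caused_by_id))
            list(instance = row$caused_by_id, kind = row$caused_by_kind)
          else NULL,
          slice_id = row$slice_id)
      })
      medmod_slice(rows$slice_id[1], insts)
    })
    d <- medmod_dataset(model, unname(slices))
  }
  check_ids(unlist(lapply(d$slices, function(s)
    vapply(s$instances, `[[`, character(1), "instance_id"))))
  d
}

# ---- query JSON ------------------------------------------------------------

#' Read a query specification from JSON
#'
#' Top-level keys `conditions` (ordered; each `{"type": "comparison", ...}`
#' or `{"type": "aggregate", ...}`), `partitions`, `intervals`, `grouping`
#' and `retrievals`, mirroring the [pql_query()] constructor.
#'
#' @param path file path.
#' @return a `pql_query`.
#' @export
read_query <- function(path) {
  j <- json_read(path, "query")
  conds <- lapply(seq_along(j$conditions), function(i) {
    c0 <- j$conditions[[i]]
    ptr <- sprintf("/conditions/%d", i - 1L)
    type <- need(c0, "type", ptr)
    if (type == "comparison") {
      pql_comparison(need(c0, "activity", ptr), need(c0, "attribute", ptr),
                     need(c0, "op", ptr), need(c0, "value", ptr),
                     combine = c0$combine, op2 = c0$op2, value2 = c0$value2)
    } else if (type == "aggregate") {
      pql_aggregate(need(c0, "activity", ptr), need(c0, "function", ptr),
                    need(c0, "op", ptr), need(c0, "value", ptr),
                    attribute = c0$attribute)
    } else {
      abort_load(sprintf("at %s: unknown condition type '%s'", ptr, type))
    }
  })
  parts <- lapply(seq_along(j$partitions), function(i) {
    p <- j$partitions[[i]]
    ptr <- sprintf("/partitions/%d", i - 1L)
    pql_partition(need(p, "activity", ptr), need(p, "attribute", ptr),
                  need(p, "direction", ptr), need(p, "k", ptr))
  })
  ivals <- lapply(seq_along(j$intervals), function(i) {
    v <- j$intervals[[i]]
    ptr <- sprintf("/intervals/%d", i - 1L)
    pql_interval(need(v, "name", ptr),
                 need(v, "start_activity", ptr), need(v, "end_activity", ptr),
                 start_attribute = v$start_attribute,
                 end_attribute = v$end_attribute,
                 pairing = if (is.null(v$pairing)) NULL
                           else c(v$pairing$start_attribute,
                                  v$pairing$end_attribute))
  })
  grouping <- if (!is.null(j$grouping)) {
    pql_grouping(need(j$grouping, "activity", "/grouping"),
                 need(j$grouping, "attribute", "/grouping"))
  }
  retr <- lapply(seq_along(j$retrievals), function(i) {
    r <- j$retrievals[[i]]
    ptr <- sprintf("/retrievals/%d", i - 1L)
    pql_retrieval(need(r, "type", ptr), need(r, "activity", ptr),
                  attribute = r$attribute)
  })
  pql_query(conditions = conds, partitions = parts, intervals = ivals,
            grouping = grouping, retrievals = retr)
}

#' Write a query result as JSON
#'
#' Deterministic key order (counts in model activity order, aggregates in
#' request order), full-precision numbers, `null` for undefined averages.
#'
#' @param result a `pql_result` from [apply_query()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  agg <- lapply(result$aggregates, function(a)
    list(type = a$type, activity = a$activity,
         attribute = if (is.null(a$attribute)) NULL else a$attribute,
         value = if (is.na(a$value)) NULL else a$value))
  ivals <- lapply(result$intervals, function(per_slice)
    lapply(per_slice, function(v) as.list(v)))
  j <- list(n_slices = n_slices(result$dataset),
            n_instances = n_instances(result$dataset),
            counts = as.list(result$counts),
            aggregates = agg,
            intervals = ivals,
            inspection_count = result$inspection_count)
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' Export an instance table as CSV
#'
#' @param dataset a `medmod_dataset`.
#' @param activity activity name.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_instance_table <- function(dataset, activity, path) {
  tab <- instance_table(dataset, activity)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
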