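# PQL condition objects and their resolution/type rules.
#
# The operator vocabulary per attribute type mirrors spreadsheet-style
# filtering: ordered types get the six relational operators, strings get
# equality plus substring matching, booleans and enumerations only equality.

OPS_ORDERED <- c("=", "!=", ">", "<", ">=", "<=")
OPS_STRING  <- c("=", "!=", "contains", "begins_with", "ends_with")
OPS_EQ      <- c("=", "!=")

#' Comparison filtering condition
#'
#' Keeps the whole slices that contain at least one instance of `activity`
#' whose `attribute` satisfies the comparison. Following the spreadsheet
#' idiom, at most one extra comparison may be attached with a logical
#' `"AND"`/`"OR"`; both terms are evaluated on the same instance. A
#' comparison against an absent attribute value is false. Besides declared
#' attributes, `attribute` may be the reserved word `"count"` (the number of
#' instances of the activity in the slice) or the name of a time interval
#' defined in the same query.
#'
#' @param activity activity name.
#' @param attribute attribute name, `"count"`, or an interval name.
#' @param op,value comparison operator and constant (DateTime constants as
#'   ISO-8601 strings).
#' @param combine optional `"AND"` or `"OR"` joining a second term.
#' @param op2,value2 the optional second comparison.
#' @return a `pql_comparison` condition.
#' @export
pql_comparison <- function(activity, attribute, op, value,
                           combine = NULL, op2 = NULL, value2 = NULL) {
  if (!is.null(combine)) {
    combine <- toupper(combine)
    if (!combine %in% c("AND", "OR")) {
      abort_argument("combine must be 'AND' or 'OR'")
    }
    if (is.null(op2) || is.null(value2)) {
      abort_argument("combine requires op2 and value2")
    }
  } else if (!is.null(op2) || !is.null(value2)) {
    abort_argument("op2/value2 require combine")
  }
  structure(list(activity = activity, attribute = attribute,
                 op = op, value = value, combine = combine,
                 op2 = op2, value2 = value2),
            class = c("pql_comparison", "pql_condition"))
}

#' Per-slice aggregate filtering condition
#'
#' Keeps slices by a condition on the `Sum` or `Average` of an attribute over
#' the slice's instances of one activity, or on the `Count` of such
#' instances. Instances with an absent attribute value are excluded from
#' Sum/Average. A slice containing no instance of the activity always fails
#' (the filter asks for slices that contain instances of the filtered type);
#' a slice with instances but no attribute values fails Sum/Average.
#'
#' @param activity activity name.
#' @param fun `"Sum"`, `"Average"` or `"Count"`.
#' @param attribute numeric attribute name; omit for `Count`.
#' @param op,value comparison operator (ordered set) and numeric constant.
#' @return a `pql_aggregate` condition.
#' @export
pql_aggregate <- function(activity, fun, op, value, attribute = NULL) {
  if (!fun %in% c("Sum", "Average", "Count")) {
    abort_argument("fun must be Sum, Average or Count")
  }
  if (fun == "Count" && !is.null(attribute)) {
    abort_argument("Count takes no attribute")
  }
  if (fun != "Count" && is.null(attribute)) {
    abort_argument(sprintf("%s requires an attribute", fun))
  }
  structure(list(activity = activity, fun = fun, attribute = attribute,
                 op = op, value = value),
            class = c("pql_aggregate", "pql_condition"))
}

#' Top/Bottom-k data partitioning condition
#'
#' Ranks slices by the extreme value of `attribute` over their instances of
#' `activity` (maximum for `Top`, minimum for `Bottom`), breaks ties by
#' ascending slice id, and keeps the first `k` whole slices. Slices with no
#' valued instance of the activity are unranked and dropped. Partitions are
#' applied to the dataset left by the comparison/aggregate conditions, and
#' multiple partitions intersect.
#'
#' @param activity activity name.
#' @param attribute numeric or DateTime attribute (or interval name).
#' @param direction `"Top"` or `"Bottom"`.
#' @param k positive integer, at most `k_max` (see [evaluate_partition()]).
#' @return a `pql_partition` condition.
#' @export
pql_partition <- function(activity, attribute, direction, k) {
  if (!direction %in% c("Top", "Bottom")) {
    abort_argument("direction must be Top or Bottom")
  }
  structure(list(activity = activity, attribute = attribute,
                 direction = direction, k = as.integer(k)),
            class = c("pql_partition", "pql_condition"))
}

#' Time interval definition
#'
#' A derived attribute of the slice: the difference in seconds between an end
#' activity's timestamp and a start activity's timestamp. Multiple interval
#' values can arise when the slice holds multiple start/end instances; an
#' optional pairing condition (equality between a start-instance attribute
#' and an end-instance attribute, e.g. matching procedure codes) restricts
#' which instances are paired. Within each pairing class, each start is
#' matched to the earliest not-yet-paired end at or after it, so durations
#' are never negative. Once defined, the interval name can be used in
#' filtering conditions like an attribute.
#'
#' @param name interval name, unique within the query.
#' @param start_activity,end_activity activity names.
#' @param start_attribute,end_attribute optional DateTime attributes; the
#'   default is the instance's intrinsic start time.
#' @param pairing optional `c(start_attr, end_attr)` equality pair.
#' @return a `pql_interval` definition.
#' @export
pql_interval <- function(name, start_activity, end_activity,
                         start_attribute = NULL, end_attribute = NULL,
                         pairing = NULL) {
  if (!is.null(pairing) && length(pairing) != 2L) {
    abort_argument("pairing must be c(start_attribute, end_attribute)")
  }
  structure(list(name = name,
                 start_activity = start_activity,
                 start_attribute = start_attribute,
                 end_activity = end_activity,
                 end_attribute = end_attribute,
                 pairing = pairing),
            class = "pql_interval")
}

#' Slice grouping definition
#'
#' Merges slices that share an attribute value (e.g. a patient's surname) on
#' instances of one activity into a single group-slice, so that intervals can
#' be measured across a patient's multiple appearances. A slice holding
#' several different key values is assigned to the key of its earliest keyed
#' instance; slices without the attribute stay singleton groups.
#'
#' @param activity activity name.
#' @param attribute grouping attribute on that activity.
#' @return a `pql_grouping` definition.
#' @export
pql_grouping <- function(activity, attribute) {
  structure(list(activity = activity, attribute = attribute),
            class = "pql_grouping")
}

#' Data retrieval request
#'
#' @param type `"count"`, `"sum"`, `"average"` (single-number indicators) or
#'   `"table"` (the list of all instances of an activity).
#' @param activity activity name.
#' @param attribute attribute name for sum/average.
#' @return a `pql_retrieval` request.
#' @export
pql_retrieval <- function(type, activity, attribute = NULL) {
  type <- tolower(type)
  if (!type %in% c("count", "sum", "average", "table")) {
    abort_argument("retrieval type must be count, sum, average or table")
  }
  structure(list(type = type, activity = activity, attribute = attribute),
            class = "pql_retrieval")
}

#' Assemble a query
#'
#' The declarative equivalent of the interactive query diagram: an ordered
#' list of comparison/aggregate filtering conditions, a set of partitioning
#' conditions, interval definitions, an optional grouping, and retrieval
#' requests. See [apply_query()] for the evaluation order.
#'
#' @param conditions ordered list of [pql_comparison()] / [pql_aggregate()].
#' @param partitions list of [pql_partition()].
#' @param intervals list of [pql_interval()].
#' @param grouping optional [pql_grouping()].
#' @param retrievals list of [pql_retrieval()].
#' @return a `pql_query` object.
#' @export
pql_query <- function(conditions = list(), partitions = list(),
                      intervals = list(), grouping = NULL,
                      retrievals = list()) {
  if (inherits(conditions, "pql_condition")) conditions <- list(conditions)
  if (inherits(partitions, "pql_partition")) partitions <- list(partitions)
  if (inherits(intervals, "pql_interval")) intervals <- list(intervals)
  if (inherits(retrievals, "pql_retrieval")) retrievals <- list(retrievals)
  inames <- vapply(intervals, `[[`, character(1), "name")
  if (anyDuplicated(inames)) abort_argument("interval names must be unique")
  structure(list(conditions = conditions, partitions = partitions,
                 intervals = intervals, grouping = grouping,
                 retrievals = retrievals),
            class = "pql_query")
}

# ---- resolution ------------------------------------------------------------

legal_ops <- function(type) {
  if (type %in% c("Integer", "Real", "DateTime", "count", "interval")) {
    OPS_ORDERED
  } else if (type == "String") {
    OPS_STRING
  } else {
    OPS_EQ  # Boolean and enumerations
  }
}

# Resolve the attribute of a condition to an effective type. `derived` is a
# character vector of interval names usable as Real-valued attributes.
resolve_attr_type <- function(model, activity, attribute,
                              derived = character(0)) {
  if (is.null(get_activity(model, activity))) {
    abort_resolution(sprintf("unknown activity '%s'", activity))
  }
  if (identical(attribute, "count")) return("count")
  if (attribute %in% derived) return("interval")
  at <- get_attribute(model, activity, attribute)
  if (is.null(at)) {
    abort_resolution(sprintf("unknown attribute '%s' on activity '%s'",
                             attribute, activity))
  }
  at$type
}

# Coerce/validate one comparison constant against the effective type;
# DateTime constants arrive as ISO-8601 strings.
resolve_constant <- function(value, type, model) {
  if (type %in% c("Integer", "Real", "count", "interval")) {
    if (!is.numeric(value)) abort_type("numeric constant required")
    return(as.numeric(value))
  }
  if (type == "DateTime") {
    if (is.character(value)) return(parse_time(value))
    if (is.numeric(value)) return(as.numeric(value))
    abort_type("DateTime constant must be ISO-8601 or epoch seconds")
  }
  if (type == "Boolean") {
    if (!is.logical(value)) abort_type("Boolean constant required")
    return(value)
  }
  if (type == "String") {
    if (!is.character(value)) abort_type("String constant required")
    return(value)
  }
  lits <- model$enumerations[[type]]
  if (!is.character(value) || !value %in% lits) {
    abort_type(sprintf("'%s' is not a literal of enumeration '%s'",
                       as.character(value), type))
  }
  value
}

# Returns the condition with parsed constants and a per-term comparator,
# ready for instance-level evaluation.
resolve_comparison <- function(model, cond, derived = character(0)) {
  type <- resolve_attr_type(model, cond$activity, cond$attribute, derived)
  check_op <- function(op) {
    if (!op %in% legal_ops(type)) {
      abort_type(sprintf("operator '%s' not legal for type %s", op, type))
    }
  }
  check_op(cond$op)
  cond$value <- resolve_constant(cond$value, type, model)
  if (!is.null(cond$combine)) {
    check_op(cond$op2)
    cond$value2 <- resolve_constant(cond$value2, type, model)
  }
  cond$type <- type
  cond
}

resolve_aggregate <- function(model, cond, derived = character(0)) {
  if (is.null(get_activity(model, cond$activity))) {
    abort_resolution(sprintf("unknown activity '%s'", cond$activity))
  }
  if (!cond$op %in% OPS_ORDERED) {
    abort_type(sprintf("operator '%s' not legal for aggregate conditions",
                       cond$op))
  }
  if (!is.numeric(cond$value)) abort_type("numeric constant required")
  if (cond$fun != "Count") {
    type <- resolve_attr_type(model, cond$activity, cond$attribute, derived)
    if (!type %in% c("Integer", "Real", "interval")) {
      abort_type(sprintf("%s requires a numeric attribute, '%s' is %s",
                         cond$fun, cond$attribute, type))
    }
  }
  cond
}

resolve_partition <- function(model, cond, k_max, derived = character(0)) {
  if (is.na(cond$k) || cond$k < 1L || cond$k > k_max) {
    abort_argument(sprintf("k must be in [1, %d], got %s", k_max, cond$k))
  }
  type <- resolve_attr_type(model, cond$activity, cond$attribute, derived)
  if (!type %in% c("Integer", "Real", "DateTime", "interval")) {
    abort_type(sprintf("partitioning requires a numeric or DateTime attribute, '%s' is %s",
                       cond$attribute, type))
  }
  cond
}

# ---- value-level comparison ------------------------------------------------

# Exact (IEEE) semantics, no tolerance; strings case-sensitive. `x` may be a
# multi-valued derived attribute: the term holds if any value satisfies it.
compare_values <- function(x, op, const) {
  if (is.null(x) || length(x) == 0L) return(FALSE)
  if (all(is.na(x))) return(FALSE)
  x <- x[!is.na(x)]
  r <- switch(op,
              "="  = x == const,
              "!=" = x != const,
              ">"  = x > const,
              "<"  = x < const,
              ">=" = x >= const,
              "<=" = x <= const,
              "contains"    = grepl(const, x, fixed = TRUE),
              "begins_with" = startsWith(x, const),
              "ends_with"   = endsWith(x, const),
              abort_type(sprintf("unknown operator '%s'", op)))
  any(r)
}

# Evaluate a resolved comparison condition on one instance (both terms on the
# same instance). `count_value` supplies the per-slice instance count when
# the reserved attribute "count" is used.
instance_matches <- function(inst, cond, count_value = NULL) {
  if (inst$activity != cond$activity) return(FALSE)
  x <- if (identical(cond$type, "count")) count_value
       else inst$attrs[[cond$attribute]]
  r1 <- compare_values(x, cond$op, cond$value)
  if (is.null(cond$combine)) return(r1)
  r2 <- compare_values(x, cond$op2, cond$value2)
  if (cond$combine == "AND") r1 && r2 else r1 || r2
}
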