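# The MedMod metamodel: activities with typed attributes connected by four
# relation kinds. A model is a plain S3 list; well-formedness is checked by
# validate_model(), never by the constructors (parsing and validation are
# deliberately separate so a broken model can still be loaded and inspected).

PRIMITIVE_TYPES <- c("Integer", "Real", "String", "Boolean", "DateTime")
EDGE_KINDS <- c("follows", "composition", "interruption", "extension")
CARDINALITIES <- c("1", "0..1", "1..*", "*")

#' Define an activity attribute
#'
#' @param name attribute name, unique within its activity.
#' @param type one of `Integer`, `Real`, `String`, `Boolean`, `DateTime`,
#'   or the name of an enumeration declared on the model.
#' @return an `AttributeDef` list.
#' @export
medmod_attribute <- function(name, type) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(type), length(type) == 1L)
  structure(list(name = name, type = type), class = "medmod_attribute")
}

#' Define an activity
#'
#' Activities are the nodes of a MedMod diagram: named tasks in time with a
#' start and an end moment, carrying typed attributes whose values are set on
#' run-time instances. Exactly one activity per model is the master: every one
#' of its instances roots a transaction (a slice).
#'
#' @param name activity name, unique within the model.
#' @param attributes list of [medmod_attribute()] definitions.
#' @param master logical; is this the master activity?
#' @return an `ActivityDef` list.
#' @export
medmod_activity <- function(name, attributes = list(), master = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(master), length(master) == 1L)
  if (inherits(attributes, "medmod_attribute")) attributes <- list(attributes)
  structure(list(name = name, attributes = attributes, master = isTRUE(master)),
            class = "medmod_activity")
}

#' Define an edge between two activities
#'
#' Four kinds of oriented relation:
#' \describe{
#'   \item{follows}{the target can only start after the source has ended;
#'     several outgoing follows edges from one activity are exclusive (XOR),
#'     several incoming edges are inclusive (OR).}
#'   \item{composition}{the source (aggregate) semantically consists of
#'     instances of the target (component); a cardinality on the component
#'     end bounds how many may appear per aggregate instance (default `"1"`).}
#'   \item{interruption}{executing the target suspends the source: the source
#'     may create no new component instances afterwards, but components
#'     already running finish normally.}
#'   \item{extension}{the target can be called at some time during the
#'     execution of the source, guarded by an extension-point condition.}
#' }
#'
#' @param kind one of `"follows"`, `"composition"`, `"interruption"`,
#'   `"extension"`.
#' @param source,target activity names.
#' @param cardinality composition only: one of `"1"`, `"0..1"`, `"1..*"`, `"*"`.
#' @param extension_point extension only: the guard condition's name.
#' @return an `Edge` list.
#' @export
medmod_edge <- function(kind, source, target,
                        cardinality = NULL, extension_point = NULL) {
  kind <- tolower(kind)
  if (!kind %in% EDGE_KINDS) {
    abort_structural(sprintf("unknown edge kind '%s'", kind))
  }
  if (!is.null(cardinality) && kind != "composition") {
    abort_structural("cardinality is only allowed on composition edges")
  }
  if (!is.null(extension_point) && kind != "extension") {
    abort_structural("extension_point is only allowed on extension edges")
  }
  if (kind == "composition" && is.null(cardinality)) cardinality <- "1"
  if (!is.null(cardinality) && !cardinality %in% CARDINALITIES) {
    abort_structural(sprintf("unknown cardinality '%s'", cardinality))
  }
  structure(list(kind = kind, source = source, target = target,
                 cardinality = cardinality, extension_point = extension_point),
            class = "medmod_edge")
}

#' Assemble a process model
#'
#' @param name model name.
#' @param activities list of [medmod_activity()].
#' @param edges list of [medmod_edge()].
#' @param enumerations named list mapping enumeration name to a character
#'   vector of literals.
#' @return a `medmod_model` object. Run [validate_model()] to check
#'   well-formedness; construction itself only requires structural sanity.
#' @export
medmod_model <- function(name, activities = list(), edges = list(),
                         enumerations = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(enumerations) && is.null(names(enumerations))) {
    abort_structural("enumerations must be a named list")
  }
  m <- structure(list(name = name,
                      enumerations = enumerations,
                      activities = activities,
                      edges = edges),
                 class = "medmod_model")
  m
}

activity_names <- function(model) {
  vapply(model$activities, `[[`, character(1), "name")
}

master_activity <- function(model) {
  flags <- vapply(model$activities, function(a) isTRUE(a$master), logical(1))
  if (sum(flags) != 1L) return(NULL)
  model$activities[[which(flags)]]$name
}

get_activity <- function(model, name) {
  for (a in model$activities) if (a$name == name) return(a)
  NULL
}

get_attribute <- function(model, activity, attribute) {
  a <- get_activity(model, activity)
  if (is.null(a)) return(NULL)
  for (at in a$attributes) if (at$name == attribute) return(at)
  NULL
}

# Activities that are the source of >= 1 composition edge.
aggregate_activities <- function(model) {
  unique(vapply(Filter(function(e) e$kind == "composition", model$edges),
                `[[`, character(1), "source"))
}

violation <- function(rule, severity, element, message) {
  data.frame(rule = rule, severity = severity, element = element,
             message = message, stringsAsFactors = FALSE)
}

empty_violations <- function() {
  data.frame(rule = character(0), severity = character(0),
             element = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a process model for well-formedness
#'
#' Checks the structural rules of the language:
#' \describe{
#'   \item{V1}{exactly one activity is flagged as master.}
#'   \item{V2}{no edge of any kind targets the master (it has no ingoing
#'     arrows).}
#'   \item{V3}{duplicate follows edges (same source and target twice) are
#'     violations; multiple distinct outgoing follows edges are legal XOR
#'     alternatives.}
#'   \item{V4}{an interruption out of a non-aggregate source is reported as a
#'     warning (suspending an activity with no unbounded component behavior
#'     is legal but unusual).}
#'   \item{V5}{the composition graph is acyclic and every component has
#'     exactly one aggregate parent.}
#'   \item{V6}{every edge endpoint and every attribute's enumeration
#'     reference resolves.}
#'   \item{V7}{activity names, enumeration names, attribute names within an
#'     activity, and literals within an enumeration are unique.}
#' }
#'
#' @param model a [medmod_model()].
#' @return a data frame of violation records with columns `rule`, `severity`
#'   (`"error"` or `"warning"`), `element` and `message`; zero rows means the
#'   model is well-formed. Deterministic and side-effect free.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "medmod_model")) {
    abort_structural("not a medmod_model object")
  }
  v <- list(empty_violations())
  acts <- activity_names(model)

  # V7 uniqueness
  dup <- unique(acts[duplicated(acts)])
  for (d in dup) {
    v[[length(v) + 1L]] <- violation("V7", "error", d,
      sprintf("activity name '%s' is not unique", d))
  }
  enames <- names(model$enumerations)
  for (d in unique(enames[duplicated(enames)])) {
    v[[length(v) + 1L]] <- violation("V7", "error", d,
      sprintf("enumeration name '%s' is not unique", d))
  }
  for (en in enames) {
    lits <- model$enumerations[[en]]
    if (length(lits) < 1L) {
      v[[length(v) + 1L]] <- violation("V7", "error", en,
        sprintf("enumeration '%s' has no literals", en))
    }
    if (anyDuplicated(lits)) {
      v[[length(v) + 1L]] <- violation("V7", "error", en,
        sprintf("enumeration '%s' has duplicate literals", en))
    }
  }
  for (a in model$activities) {
    ats <- vapply(a$attributes, `[[`, character(1), "name")
    for (d in unique(ats[duplicated(ats)])) {
      v[[length(v) + 1L]] <- violation("V7", "error", a$name,
        sprintf("attribute '%s' duplicated on activity '%s'", d, a$name))
    }
  }

  # V1 exactly one master
  n_master <- sum(vapply(model$activities, function(a) isTRUE(a$master),
                         logical(1)))
  if (n_master != 1L) {
    v[[length(v) + 1L]] <- violation("V1", "error", model$name,
      sprintf("model must have exactly one master activity, found %d",
              n_master))
  }
  master <- master_activity(model)

  # V6 endpoint / enumeration resolution
  for (e in model$edges) {
    for (side in c("source", "target")) {
      if (!e[[side]] %in% acts) {
        v[[length(v) + 1L]] <- violation("V6", "error", e[[side]],
          sprintf("%s edge %s '%s' does not resolve to an activity",
                  e$kind, side, e[[side]]))
      }
    }
  }
  for (a in model$activities) {
    for (at in a$attributes) {
      if (!at$type %in% PRIMITIVE_TYPES && !at$type %in% enames) {
        v[[length(v) + 1L]] <- violation("V6", "error",
          paste0(a$name, ".", at$name),
          sprintf("attribute type '%s' is neither primitive nor a declared enumeration",
                  at$type))
      }
    }
  }

  # V2 nothing targets the master
  if (!is.null(master)) {
    for (e in model$edges) {
      if (e$target == master) {
        v[[length(v) + 1L]] <- violation("V2", "error", master,
          sprintf("%s edge from '%s' targets the master activity", e$kind,
                  e$source))
      }
    }
  }

  # V3 duplicate follows pairs
  fol <- Filter(function(e) e$kind == "follows", model$edges)
  if (length(fol)) {
    pairs <- vapply(fol, function(e) paste0(e$source, "\r", e$target),
                    character(1))
    for (p in unique(pairs[duplicated(pairs)])) {
      st <- strsplit(p, "\r", fixed = TRUE)[[1]]
      v[[length(v) + 1L]] <- violation("V3", "error", st[1],
        sprintf("duplicate follows edge '%s' -> '%s'", st[1], st[2]))
    }
  }

  # V4 interruption from a non-aggregate: warning only
  aggs <- aggregate_activities(model)
  for (e in model$edges) {
    if (e$kind == "interruption" && e$source %in% acts &&
        !e$source %in% aggs) {
      v[[length(v) + 1L]] <- violation("V4", "warning", e$source,
        sprintf("interruption out of non-aggregate activity '%s'", e$source))
    }
  }

  # V5 composition acyclic, single parent per component
  comp <- Filter(function(e) e$kind == "composition", model$edges)
  if (length(comp)) {
    tgts <- vapply(comp, `[[`, character(1), "target")
    for (d in unique(tgts[duplicated(tgts)])) {
      v[[length(v) + 1L]] <- violation("V5", "error", d,
        sprintf("component '%s' has more than one aggregate parent", d))
    }
    # cycle detection: repeatedly drop edges into pure sinks; edges that
    # survive lie on a cycle
    edges <- lapply(comp, function(e) c(e$source, e$target))
    repeat {
      srcs <- vapply(edges, `[`, character(1), 1)
      dsts <- vapply(edges, `[`, character(1), 2)
      keep <- dsts %in% srcs
      if (all(keep) || !length(edges)) break
      edges <- edges[keep]
    }
    if (length(edges)) {
      cyc <- unique(unlist(edges))
      v[[length(v) + 1L]] <- violation("V5", "error",
        paste(sort(cyc), collapse = ","),
        "composition graph contains a cycle")
    }
  }

  do.call(rbind, v)
}

#' @export
print.medmod_model <- function(x, ...) {
  cat(sprintf("MedMod process model '%s'\n", x$name))
  cat(sprintf("  %d activities, %d edges, %d enumerations\n",
              length(x$activities), length(x$edges), length(x$enumerations)))
  m <- master_activity(x)
  if (!is.null(m)) cat(sprintf("  master: '%s'\n", m))
  invisible(x)
}
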