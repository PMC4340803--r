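# Structured condition classes. Every user-facing failure mode gets its own
# class so callers (and the CLI) can map it to a machine-readable error code.

medmod_abort <- function(message, class, call = sys.call(-1), data = list()) {
  cond <- errorCondition(message,
                         class = c(class, "medmod_error"),
                         call = call)
  cond[names(data)] <- data
  stop(cond)
}

#' @noRd
abort_structural <- function(message, ...) {
  medmod_abort(message, "medmod_structural_error", data = list(...))
}

#' @noRd
abort_resolution <- function(message, ...) {
  medmod_abort(message, "medmod_resolution_error", data = list(...))
}

#' @noRd
abort_type <- function(message, ...) {
  medmod_abort(message, "medmod_type_error", data = list(...))
}

#' @noRd
abort_argument <- function(message, ...) {
  medmod_abort(message, "medmod_argument_error", data = list(...))
}

#' @noRd
abort_config <- function(message, ...) {
  medmod_abort(message, "medmod_config_error", data = list(...))
}

#' @noRd
abort_load <- function(message, ...) {
  medmod_abort(message, "medmod_load_error", data = list(...))
}
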