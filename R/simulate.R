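# Stochastic execution of a process model: generate synthetic, conformant
# trace datasets. The generator realizes the runtime semantics of the four
# relation kinds — follows successors start after their predecessor ends and
# XOR branches are sampled by weights; aggregates spawn component instances
# until an interruption instance is sampled, after which no new components
# start; extensions fire within the host's time span with a configured
# probability. Conformance (validate_trace == no violations) holds by
# construction; identical (model, config) including the seed reproduce the
# trace exactly.

#' Distribution specifications for the simulator
#'
#' The simulator draws every random quantity from one of a small closed
#' vocabulary of distributions: `constant`, `uniform` (optionally rounded to
#' `digits`), `uniform_int`, `exponential`, and `categorical` over explicit
#' values with weights.
#'
#' @param value constant value.
#' @param min,max range bounds.
#' @param digits optional rounding for `dist_uniform` draws.
#' @param rate exponential rate (mean `1/rate`).
#' @param values,weights categorical support and probabilities (weights are
#'   normalized; default uniform).
#' @return a `medmod_dist` specification.
#' @name distributions
NULL

#' @rdname distributions
#' @export
dist_constant <- function(value) {
  structure(list(kind = "constant", value = value), class = "medmod_dist")
}

#' @rdname distributions
#' @export
dist_uniform <- function(min, max, digits = NULL) {
  if (!(is.numeric(min) && is.numeric(max) && min <= max)) {
    abort_config("dist_uniform requires numeric min <= max")
  }
  structure(list(kind = "uniform", min = min, max = max, digits = digits),
            class = "medmod_dist")
}

#' @rdname distributions
#' @export
dist_uniform_int <- function(min, max) {
  if (!(is.numeric(min) && is.numeric(max) && min <= max)) {
    abort_config("dist_uniform_int requires numeric min <= max")
  }
  structure(list(kind = "uniform_int", min = as.integer(min),
                 max = as.integer(max)), class = "medmod_dist")
}

#' @rdname distributions
#' @export
dist_exponential <- function(rate) {
  if (!is.numeric(rate) || rate <= 0) {
    abort_config("dist_exponential requires rate > 0")
  }
  structure(list(kind = "exponential", rate = rate), class = "medmod_dist")
}

#' @rdname distributions
#' @export
dist_categorical <- function(values, weights = NULL) {
  if (!length(values)) abort_config("dist_categorical requires values")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0) ||
      sum(weights) <= 0) {
    abort_config("categorical weights must be non-negative, same length as values")
  }
  structure(list(kind = "categorical", values = values,
                 weights = weights / sum(weights)), class = "medmod_dist")
}

draw_dist <- function(spec, n = 1L) {
  switch(spec$kind,
         constant = rep(spec$value, n),
         uniform = {
           x <- stats::runif(n, spec$min, spec$max)
           if (!is.null(spec$digits)) x <- round(x, spec$digits)
           x
         },
         uniform_int = as.numeric(spec$min +
           (sample.int(spec$max - spec$min + 1L, n, replace = TRUE) - 1L)),
         exponential = stats::rexp(n, spec$rate),
         categorical = spec$values[sample.int(length(spec$values), n,
                                              replace = TRUE,
                                              prob = spec$weights)],
         abort_config(sprintf("unknown distribution kind '%s'", spec$kind)))
}

#' Simulation configuration
#'
#' Everything the generator needs beyond the model itself. Weight maps are
#' keyed by activity (branch choices) or `"source->target"` (extension
#' probabilities, composition counts, attribute copying).
#'
#' @param n_slices number of transactions to generate (>= 0).
#' @param seed RNG seed; identical seeds reproduce the trace byte for byte.
#' @param time_origin ISO-8601 start of the observation window.
#' @param inter_arrival distribution of seconds between consecutive master
#'   instance starts.
#' @param branch_weights named list: source activity -> named weight vector
#'   over target activities, used for XOR follows choices and for choosing
#'   among several interruption edges; each vector must sum to 1. Activities
#'   with a single outgoing edge need no entry.
#' @param extension_prob named list: `"source->target"` -> probability that
#'   the extension fires during one host instance.
#' @param composition_counts named list: `"aggregate->component"` ->
#'   distribution of realized component counts; draws are clamped into the
#'   declared cardinality bounds.
#' @param durations named list: activity -> duration distribution (seconds);
#'   `default_duration` is used for activities without an entry.
#' @param default_duration fallback duration distribution.
#' @param attributes named list: `"activity.attribute"` -> value generator.
#'   Attributes without a generator stay absent.
#' @param inherit named list: `"source->target"` -> character vector of
#'   attribute names copied from the causal predecessor instance (e.g. the
#'   procedure code carried from assignment to execution).
#' @param follow_delay distribution of the gap between a predecessor's end
#'   and a follows-successor's start.
#' @param component_gap distribution of the gap between consecutive
#'   component spawns within an aggregate.
#' @param interruption_delay distribution of the gap between the last
#'   component spawn and the interrupting instance's start.
#' @param max_slice_instances safety budget per slice; exceeding it (e.g. a
#'   follows cycle) is a configuration error.
#' @return a `medmod_sim_config` object.
#' @export
sim_config <- function(n_slices,
                       seed = 1L,
                       time_origin = "2012-01-01T08:00:00Z",
                       inter_arrival = dist_exponential(1 / 1800),
                       branch_weights = list(),
                       extension_prob = list(),
                       composition_counts = list(),
                       durations = list(),
                       default_duration = dist_uniform(600, 3600),
                       attributes = list(),
                       inherit = list(),
                       follow_delay = dist_uniform(300, 1800),
                       component_gap = dist_uniform(1800, 14400),
                       interruption_delay = dist_uniform(3600, 14400),
                       max_slice_instances = 1000L) {
  if (!is.numeric(n_slices) || length(n_slices) != 1L || n_slices < 0) {
    abort_config("n_slices must be a non-negative integer")
  }
  for (src in names(branch_weights)) {
    w <- branch_weights[[src]]
    if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      abort_config(sprintf(
        "branch weights for '%s' must be named, non-negative and sum to 1",
        src))
    }
  }
  for (p in unlist(extension_prob)) {
    if (p < 0 || p > 1) abort_config("extension probabilities must be in [0, 1]")
  }
  structure(list(n_slices = as.integer(n_slices), seed = as.integer(seed),
                 time_origin = time_origin, inter_arrival = inter_arrival,
                 branch_weights = branch_weights,
                 extension_prob = extension_prob,
                 composition_counts = composition_counts,
                 durations = durations, default_duration = default_duration,
                 attributes = attributes, inherit = inherit,
                 follow_delay = follow_delay, component_gap = component_gap,
                 interruption_delay = interruption_delay,
                 max_slice_instances = as.integer(max_slice_instances)),
            class = "medmod_sim_config")
}

clamp_count <- function(k, cardinality) {
  switch(cardinality,
         "1"    = 1L,
         "0..1" = min(max(k, 0L), 1L),
         "1..*" = max(k, 1L),
         "*"    = max(k, 0L))
}

pick_target <- function(config, source, targets) {
  if (length(targets) == 1L) return(targets)
  w <- config$branch_weights[[source]]
  if (is.null(w)) w <- stats::setNames(rep(1 / length(targets),
                                           length(targets)), targets)
  if (!all(targets %in% names(w))) {
    abort_config(sprintf("branch weights for '%s' must cover targets: %s",
                         source, paste(targets, collapse = ", ")))
  }
  sample(targets, 1L, prob = w[targets])
}

#' Simulate a process model into a synthetic trace dataset
#'
#' @param model a valid [medmod_model()].
#' @param config a [sim_config()].
#' @return a `medmod_dataset` of `config$n_slices` slices, each rooted at one
#'   master instance, that passes [validate_trace()] with zero violations.
#' @examples
#' d <- simulate_trace(demo_model(), demo_config(n_slices = 5, seed = 42))
#' n_slices(d)
#' @export
simulate_trace <- function(model, config) {
  stopifnot(inherits(model, "medmod_model"),
            inherits(config, "medmod_sim_config"))
  mv <- validate_model(model)
  if (any(mv$severity == "error")) {
    abort_config("model is not well-formed; run validate_model()")
  }
  set.seed(config$seed)
  master <- master_activity(model)

  out_follows <- split(
    vapply(Filter(function(e) e$kind == "follows", model$edges),
           `[[`, character(1), "target"),
    vapply(Filter(function(e) e$kind == "follows", model$edges),
           `[[`, character(1), "source"))
  out_interrupt <- split(
    vapply(Filter(function(e) e$kind == "interruption", model$edges),
           `[[`, character(1), "target"),
    vapply(Filter(function(e) e$kind == "interruption", model$edges),
           `[[`, character(1), "source"))
  out_comp <- Filter(function(e) e$kind == "composition", model$edges)
  out_ext <- Filter(function(e) e$kind == "extension", model$edges)

  duration_of <- function(activity) {
    d <- config$durations[[activity]]
    if (is.null(d)) config$default_duration else d
  }
  gen_attrs <- function(activity) {
    act <- get_activity(model, activity)
    attrs <- list()
    for (at in act$attributes) {
      g <- config$attributes[[paste0(activity, ".", at$name)]]
      if (!is.null(g)) attrs[[at$name]] <- draw_dist(g, 1L)
    }
    attrs
  }

  # Whole-second timestamps: the wire dialects print seconds, so integer
  # times make write/read round-trips exact.
  t0 <- parse_time(config$time_origin)
  arrivals <- round(t0 + cumsum(draw_dist(config$inter_arrival,
                                          config$n_slices)))
  slices <- vector("list", config$n_slices)

  for (s in seq_len(config$n_slices)) {
    sid <- sprintf("S%05d", s)
    env <- new.env(parent = emptyenv())
    env$insts <- list()
    env$counter <- 0L

    exec <- function(activity, start, caused_by, pred = NULL) {
      env$counter <- env$counter + 1L
      if (env$counter > config$max_slice_instances) {
        abort_config(
          "slice instance budget exceeded; does the model contain a follows cycle?")
      }
      iid <- sprintf("%s-i%03d", sid, env$counter)
      start <- round(start)
      end <- round(start + draw_dist(duration_of(activity), 1L))
      attrs <- gen_attrs(activity)
      if (!is.null(pred)) {
        copy <- config$inherit[[paste0(pred$activity, "->", activity)]]
        for (an in copy) attrs[[an]] <- pred$attrs[[an]]
      }
      self_idx <- length(env$insts) + 1L
      rec <- medmod_instance(iid, activity, start, end, attrs, caused_by, sid)
      env$insts[[self_idx]] <- rec

      # composition: spawn components, then sample the interruption
      my_comp <- Filter(function(e) e$source == activity, out_comp)
      if (length(my_comp)) {
        spawn_types <- character(0)
        for (e in my_comp) {
          cd <- config$composition_counts[[paste0(e$source, "->", e$target)]]
          k <- if (is.null(cd)) 1L else as.integer(draw_dist(cd, 1L))
          k <- clamp_count(k, e$cardinality)
          spawn_types <- c(spawn_types, rep(e$target, k))
        }
        if (length(spawn_types) > 1L) {
          spawn_types <- sample(spawn_types)  # interleave component kinds
        }
        t_spawn <- round(start + cumsum(draw_dist(config$component_gap,
                                                  length(spawn_types))))
        last_spawn <- if (length(t_spawn)) max(t_spawn) else start
        for (j in seq_along(spawn_types)) {
          kid <- exec(spawn_types[j], t_spawn[j],
                      list(instance = iid, kind = "composition"), rec)
          end <- max(end, kid$end)
        }
        ints <- out_interrupt[[activity]]
        if (!is.null(ints)) {
          tgt <- pick_target(config, activity, ints)
          t_int <- round(last_spawn + draw_dist(config$interruption_delay, 1L))
          int_inst <- exec(tgt, t_int,
                           list(instance = iid, kind = "interruption"), rec)
          end <- max(end, int_inst$start)
        }
      }

      # extensions fire inside the host's (possibly extended) span
      for (e in Filter(function(x) x$source == activity, out_ext)) {
        p <- config$extension_prob[[paste0(e$source, "->", e$target)]]
        if (is.null(p)) p <- 0
        if (stats::runif(1) < p) {
          t_ext <- round(stats::runif(1, start, max(end, start)))
          exec(e$target, t_ext, list(instance = iid, kind = "extension"), rec)
        }
      }

      # follows: XOR choice among outgoing flows, successor after our end
      succ <- out_follows[[activity]]
      if (!is.null(succ)) {
        tgt <- pick_target(config, activity, succ)
        t_next <- round(end + draw_dist(config$follow_delay, 1L))
        exec(tgt, t_next, list(instance = iid, kind = "follows"), rec)
      }

      rec$end <- end
      env$insts[[self_idx]] <- rec
      rec
    }

    exec(master, arrivals[s], NULL, NULL)
    slices[[s]] <- medmod_slice(sid, env$insts)
  }
  medmod_dataset(model, slices)
}

#' @export
print.medmod_sim_config <- function(x, ...) {
  cat(sprintf("MedMod simulation config: %d slices, seed %d, origin %s\n",
              x$n_slices, x$seed, x$time_origin))
  invisible(x)
}
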