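# Condition helpers. Error classes map to distinct CLI exit codes:
# input 2, domain 3, estimation 4, simulation 5, no-tail 6.

stop_domain <- function(msg, ...) {
  rlang::abort(msg, class = "repeatburst_domain_error", ...)
}

stop_domain_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop_domain(msg, ...)
  invisible(NULL)
}

stop_input <- function(msg, ...) {
  rlang::abort(msg, class = "repeatburst_input_error", ...)
}

stop_estimation <- function(msg, ...) {
  rlang::abort(msg, class = "repeatburst_estimation_error", ...)
}

stop_simulation <- function(msg, ...) {
  rlang::abort(msg, class = "repeatburst_simulation_error", ...)
}

stop_no_tail <- function(msg, ...) {
  rlang::abort(msg, class = c("repeatburst_no_tail_error",
                              "repeatburst_domain_error"), ...)
}

# Run `expr` under a reproducible RNG state when `seed` is given, leaving the
# caller's RNG untouched; with seed = NULL the global stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stop_domain_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
                 "`seed` must be a single integer.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
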