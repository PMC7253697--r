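# Classed conditions so the CLI can map failures to exit codes:
# parameter/usage problems -> exit 1, data/format problems -> exit 2.

stop_param <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("kmerpanel_param_error", "kmerpanel_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("kmerpanel_format_error", "kmerpanel_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("kmerpanel_io_error", "kmerpanel_error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("kmerpanel_usage_error", "kmerpanel_error")))
}

# Run `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_param("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
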