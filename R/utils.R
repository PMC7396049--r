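# Boltzmann constant, kcal/(mol K)
.kB <- 0.0019872041

# Classed conditions: config errors abort before any computation (a shell
# wrapper would map them to distinct exit codes), format errors come from
# file readers, analysis errors from the numerical stages.
abort_config <- function(msg) abort(msg, class = "aquaflux_config_error")
abort_format <- function(msg) abort(msg, class = "aquaflux_format_error")
abort_input <- function(msg) abort(msg, class = "aquaflux_input_error")
abort_analysis <- function(msg) abort(msg, class = "aquaflux_analysis_error")
abort_reference <- function(msg) abort(msg, class = "aquaflux_reference_error")
abort_scenario <- function(msg) abort(msg, class = "aquaflux_scenario_error")
abort_parameter <- function(msg) abort(msg, class = "aquaflux_parameter_error")
abort_io <- function(msg) abort(msg, class = "aquaflux_io_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream; seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_input(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort_input(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
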