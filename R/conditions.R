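# Classed conditions so callers can distinguish bad configuration from bad
# data or I/O failures programmatically.

vs_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "virtualstain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vs_config_error <- function(msg, ...) vs_error("vs_config_error", msg, ...)
vs_input_error <- function(msg, ...) vs_error("vs_input_error", msg, ...)
vs_io_error <- function(msg, ...) vs_error("vs_io_error", msg, ...)
vs_registration_error <- function(msg, ...) vs_error("vs_registration_error", msg, ...)
vs_numeric_error <- function(msg, ...) vs_error("vs_numeric_error", msg, ...)

#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package draw from a locally seeded RNG
#' so that no call mutates the caller's global RNG state.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
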