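#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), matching how
#' distances are conventionally reported to 0.1 nm. `base::round()` uses
#' banker's rounding, which is not what printed tables use.
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Deterministic per-unit seed derived from a master seed and an integer id,
# kept inside the 32-bit signed range. Order-independent across units.
derive_seed <- function(master_seed, id) {
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m)
  v <- (s * 48271 + as.numeric(id) * 16807 + 12345) %% m
  as.integer(v)
}

stop_param <- function(...) {
  stop(structure(class = c("smfretr_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_param(...)
  invisible(TRUE)
}
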