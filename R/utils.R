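# Average calendar month length in days; used to convert 7/14-day
# administration schedules onto the monthly model cycle.
DAYS_PER_MONTH <- 365.25 / 12

#' Round half away from zero
#'
#' Monetary results are reported to 2 decimals with ties rounded away from
#' zero (the convention of the published base case), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.005) # 2.01, where round(2.005, 2) gives 2
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop with a consistent error class for input validation failures
abort_invalid <- function(msg, ...) {
  abort(msg, class = "markovcea_invalid", ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_invalid(sprintf("`%s` is missing.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single number.", name))
  }
  if (x < min || x > max) {
    abort_invalid(sprintf("`%s` = %g is outside [%g, %g].", name, x, min, max))
  }
  invisible(x)
}

# deterministic per-trial seed derivation: keeps all derived seeds in
# 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}
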