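#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Round half away from zero at `digits` decimals. base::round() rounds half
# to even, which does not reproduce the conventions of registry-style tables
# (e.g. 7.545 -> 7.55, not 7.54).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(x * scale + 0.5 * sign(x)) / scale
}

# Percent of `n` over `denom`, rounded half-up; 0 (not NaN) for an empty
# denominator so empty reports render cleanly.
pct <- function(n, denom, digits = 0) {
  if (denom == 0) return(rep(0, length(n)))
  round_half_up(100 * n / denom, digits)
}

fmt_pct <- function(p, digits) {
  formatC(p, format = "f", digits = digits)
}
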