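# Trapezoidal quadrature on a grid. Accumulation via cumsum keeps the
# Monte-Carlo loop cheap; the grid need not be uniform.
cumtrapz_grid <- function(x, y) {
  n <- length(x)
  c(0, cumsum(0.5 * diff(x) * (y[-1L] + y[-n])))
}

trapz_grid <- function(x, y) {
  n <- length(x)
  sum(0.5 * diff(x) * (y[-1L] + y[-n]))
}
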