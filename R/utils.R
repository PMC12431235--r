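# trapezoidal integral on an arbitrary (here uniform) grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# linear regression R^2 between two equally sampled traces
.r_squared <- function(pred, ref) {
  fit <- stats::lm(ref ~ pred)
  summary(fit)$r.squared
}
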