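# internal helpers shared across modules

stopf <- function(fmt, ..., class = "mclsim_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

validation_error <- function(fmt, ...) stopf(fmt, ..., class = "mclsim_validation_error")
parameter_error  <- function(fmt, ...) stopf(fmt, ..., class = "mclsim_parameter_error")
format_error     <- function(fmt, ...) stopf(fmt, ..., class = "mclsim_format_error")

assert_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L)
    validation_error("'%s' must be a non-empty numeric vector", name)
  if (finite && !all(is.finite(x)))
    validation_error("'%s' must be finite", name)
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# linear interpolation that refuses silent extrapolation beyond `slack`
interp_profile <- function(x, y, xout, slack = 0) {
  lo <- min(x); hi <- max(x)
  if (min(xout) < lo - slack - 1e-12 || max(xout) > hi + slack + 1e-12)
    validation_error(
      "requested radii [%.4f, %.4f] mm exceed profile support [%.4f, %.4f] mm",
      min(xout), max(xout), lo, hi)
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Euclidean projection of a vector onto the probability simplex
# (sort-based algorithm; O(n log n))
project_simplex <- function(v) {
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_len(n) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}
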