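#' @keywords internal
"_PACKAGE"

# Condition constructor: all package errors are classed so callers can
# distinguish parameter errors from data-quality errors programmatically.
stop_corowia <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "corowia_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L])) / 2
}

# Log-normal draws parameterised by arithmetic mean and sd.
rlnorm_ms <- function(n, mean, sd) {
  s2 <- log1p((sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Draw from `fun` until the value lands in [lo, hi]; bounded retries.
draw_trunc <- function(fun, lo = -Inf, hi = Inf, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- fun()
    if (x >= lo && x <= hi) return(x)
  }
  stop_corowia("corowia_generation_error",
               sprintf("could not draw a value in [%g, %g] after %d tries",
                       lo, hi, max_tries))
}
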