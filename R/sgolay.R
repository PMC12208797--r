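#' Savitzky-Golay convolution stencil
#'
#' Weights of the least-squares polynomial filter: fitting a polynomial of
#' order \code{p} to \code{n} equally spaced samples and evaluating its
#' \code{deriv}-th derivative at the window centre is a fixed linear
#' combination of the samples. The weights are obtained from the normal
#' equations of the local fit.
#'
#' @param p polynomial order.
#' @param n window length in samples; must be odd and greater than \code{p}.
#' @param deriv derivative order (0 = smoothing).
#' @return Numeric vector of \code{n} weights for sample offsets
#'   \code{-(n-1)/2 ... (n-1)/2}, in units of samples^-deriv.
#' @examples
#' w <- sg_coefficients(2, 11)
#' sum(w)          # smoothing weights sum to 1
#' sum(w^2)        # white-noise variance reduction factor
#' @export
sg_coefficients <- function(p = 2, n = 11, deriv = 0) {
  if (n %% 2L != 1L || n <= p)
    stop_corowia("corowia_parameter_error",
                 "window length must be odd and exceed the polynomial order")
  if (deriv > p)
    stop_corowia("corowia_parameter_error",
                 "derivative order cannot exceed the polynomial order")
  m <- (n - 1L) %/% 2L
  A <- outer(seq.int(-m, m), 0:p, `^`)
  G <- solve(crossprod(A), t(A))     # (p+1) x n; row d+1 = coefficient b_d
  factorial(deriv) * G[deriv + 1L, ]
}

#' Savitzky-Golay filtering and differentiation
#'
#' Applies the least-squares polynomial filter to a uniformly sampled series.
#' Two boundary treatments are available: \code{"fit"} evaluates the
#' polynomial fitted to the first/last full window at the off-centre boundary
#' positions (the standard treatment for open-ended recordings), and
#' \code{"cyclic"} wraps the series, appropriate for a single periodic
#' ensemble-averaged beat.
#'
#' @param x numeric series.
#' @param p polynomial order.
#' @param n window length (odd).
#' @param deriv derivative order; derivatives are returned per unit time
#'   given the sampling rate \code{fs}.
#' @param fs sampling rate in Hz (used only to scale derivatives).
#' @param edge boundary treatment, \code{"fit"} or \code{"cyclic"}.
#' @return Filtered series of the same length as \code{x}.
#' @export
sg_filter <- function(x, p = 2, n = 11, deriv = 0, fs = 1,
                      edge = c("fit", "cyclic")) {
  edge <- match.arg(edge)
  N <- length(x)
  if (N < n)
    stop_corowia("corowia_insufficient_data",
                 sprintf("series length %d is below the filter window %d", N, n))
  m <- (n - 1L) %/% 2L
  w <- sg_coefficients(p, n, deriv)

  if (edge == "cyclic") {
    xp <- c(x[(N - m + 1L):N], x, x[1:m])
    y <- numeric(N)
    for (k in seq.int(-m, m))
      y <- y + w[k + m + 1L] * xp[(1L + m + k):(N + m + k)]
    return(y * fs^deriv)
  }

  y <- numeric(N)
  core <- (m + 1L):(N - m)
  for (k in seq.int(-m, m))
    y[core] <- y[core] + w[k + m + 1L] * x[core + k]

  # boundary: evaluate the end-window fits off-centre
  A <- outer(seq.int(-m, m), 0:p, `^`)
  G <- solve(crossprod(A), t(A))
  eval_fit <- function(xw, t) {
    b <- as.vector(G %*% xw)
    d <- deriv:p
    sum(b[d + 1L] * t^(d - deriv) * factorial(d) / factorial(d - deriv))
  }
  for (j in seq_len(m)) {
    y[j] <- eval_fit(x[1:n], j - (m + 1L))
    y[N - j + 1L] <- eval_fit(x[(N - n + 1L):N], (m + 1L) - j)
  }
  y * fs^deriv
}

#' Smooth a Doppler velocity trace
#'
#' Second-order Savitzky-Golay smoothing with an 11-sample window, the
#' standard pre-processing for intracoronary Doppler average-peak-velocity
#' envelopes before beat analysis. The filter is exact on locally quadratic
#' signals, so physiological velocity morphology is preserved while
#' high-frequency envelope noise is attenuated.
#'
#' @param u velocity series (cm/s).
#' @param fs sampling rate in Hz (kept for interface symmetry; the filter
#'   window is defined in samples).
#' @return Smoothed series of identical length.
#' @export
smooth_velocity <- function(u, fs = NULL) {
  if (length(u) < 11L)
    stop_corowia("corowia_insufficient_data",
                 sprintf("velocity series has %d samples; at least 11 required",
                         length(u)))
  sg_filter(u, p = 2, n = 11, deriv = 0, edge = "fit")
}
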