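#' Multi-channel coronary recording
#'
#' Container for one simultaneous recording of aortic pressure (Pa), distal
#' coronary pressure (Pd) and Doppler average peak velocity (U), possibly on
#' two native sampling grids (dual-sensor guidewire consoles commonly record
#' pressure at 200 Hz and velocity at 100 Hz).
#'
#' @param pa,pd pressure series in mmHg on the pressure grid.
#' @param u velocity series in cm/s on the velocity grid.
#' @param fs_pressure,fs_velocity sampling rates in Hz.
#' @param vessel_id identifier.
#' @param phase \code{"pre"} or \code{"post"} (PCI).
#' @param condition \code{"rest"}, \code{"hyperemia"} or \code{"continuous"}
#'   for a full run spanning the adenosine transition.
#' @param metadata free-form list (e.g. diameter stenosis, territory).
#' @return An object of class \code{vessel_recording}.
#' @export
vessel_recording <- function(pa, pd, u, fs_pressure, fs_velocity,
                             vessel_id = "V1", phase = "pre",
                             condition = "rest", metadata = list()) {
  rec <- structure(list(
    vessel_id = vessel_id,
    phase = match.arg(phase, c("pre", "post")),
    condition = match.arg(condition, c("rest", "hyperemia", "continuous")),
    pa = as.numeric(pa), pd = as.numeric(pd), u = as.numeric(u),
    fs_pressure = fs_pressure, fs_velocity = fs_velocity,
    metadata = metadata
  ), class = "vessel_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (length(rec$pa) != length(rec$pd))
    stop_corowia("corowia_format_error", "Pa and Pd must share the pressure grid")
  if (rec$fs_pressure <= 0 || rec$fs_velocity <= 0)
    stop_corowia("corowia_format_error", "sampling rates must be positive")
  dur_p <- length(rec$pa) / rec$fs_pressure
  dur_u <- length(rec$u) / rec$fs_velocity
  tol <- max(1 / rec$fs_pressure, 1 / rec$fs_velocity) + 1e-9
  if (abs(dur_p - dur_u) > tol)
    stop_corowia("corowia_format_error",
                 sprintf("channel durations differ by %.3f s (more than one sample period)",
                         abs(dur_p - dur_u)))
  if (any(rec$pa < 0) || any(rec$pd < 0))
    stop_corowia("corowia_format_error", "negative pressures in recording")
  rec
}

#' @export
print.vessel_recording <- function(x, ...) {
  cat(sprintf("<vessel_recording> %s [%s, %s]\n", x$vessel_id, x$phase, x$condition))
  cat(sprintf("  Pa/Pd: %d samples @ %g Hz (%.1f s)\n",
              length(x$pa), x$fs_pressure, length(x$pa) / x$fs_pressure))
  cat(sprintf("  U:     %d samples @ %g Hz\n", length(x$u), x$fs_velocity))
  invisible(x)
}

#' @export
plot.vessel_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  tp <- (seq_along(x$pa) - 1) / x$fs_pressure
  tu <- (seq_along(x$u) - 1) / x$fs_velocity
  graphics::plot(tp, x$pa, type = "l", xlab = "time (s)", ylab = "P (mmHg)", ...)
  graphics::lines(tp, x$pd, col = 2)
  graphics::legend("topright", c("Pa", "Pd"), col = 1:2, lty = 1, bty = "n")
  graphics::plot(tu, x$u, type = "l", xlab = "time (s)", ylab = "U (cm/s)", ...)
  invisible(x)
}
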