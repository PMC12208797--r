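MMHG_TO_PA <- 133.322   # 1 mmHg in Pascal
PEAK_UNIT <- 1e4        # reported wave peak unit: 10 kW.m-2.s-2 = 1e4 W.m-2.s-2

#' Time derivatives of the ensemble beat in SI units
#'
#' Savitzky-Golay first derivatives (order 2, window 11 samples, matching
#' the smoothing bandwidth used on the velocity envelope) of the distal
#' pressure and velocity after conversion to SI units (mmHg to Pa via
#' 133.322; cm/s to m/s). The beat is treated as periodic, so cyclic
#' boundary handling is used.
#'
#' @param beat an \code{\link{ensemble_beat}} on a uniform grid.
#' @return List with \code{dPdt} (Pa/s) and \code{dUdt} (m/s^2).
#' @export
differentiate <- function(beat) {
  dt <- diff(beat$time)
  if (max(abs(dt - dt[1])) > 1e-9)
    stop_corowia("corowia_parameter_error",
                 "ensemble beat must be on a uniform time grid")
  list(
    dPdt = sg_filter(beat$pd * MMHG_TO_PA, 2, 11, deriv = 1,
                     fs = beat$fs, edge = "cyclic"),
    dUdt = sg_filter(beat$u / 100, 2, 11, deriv = 1,
                     fs = beat$fs, edge = "cyclic")
  )
}

#' Net wave intensity profile of an ensemble beat
#'
#' Computes the net wave intensity \code{WI(t) = dP/dt * dU/dt}
#' (W.m-2.s-2) on the representative cycle, labels each sample with one of
#' the four canonical coronary wave quadrants from the signs of the two
#' derivatives (forward/backward x compression/expansion), and anchors the
#' expansion phase at the distal systolic pressure peak, extending to the
#' end of the cycle. Samples where either derivative lies within 1% of its
#' own maximum magnitude are left unlabeled (dead-band), preventing spurious
#' quadrant flips at noise level without affecting peak amplitudes.
#'
#' Quadrants: FCW (dP/dt > 0, dU/dt > 0, accelerating), BCW (> 0, < 0,
#' decelerating), FEW (< 0, < 0, decelerating), BEW (< 0, > 0, the
#' accelerating suction wave of myocardial relaxation).
#'
#' @param beat an \code{\link{ensemble_beat}}.
#' @return An object of class \code{wia_profile} with fields \code{time},
#'   \code{dPdt}, \code{dUdt}, \code{wi}, \code{quadrant},
#'   \code{expansion_start}, \code{expansion_end}, \code{fs}.
#' @export
net_wave_intensity <- function(beat) {
  d <- differentiate(beat)
  mp <- max(abs(d$dPdt)); mu <- max(abs(d$dUdt))
  if (mp == 0 || mu == 0)
    stop_corowia("corowia_degenerate_beat",
                 "flat channel: wave intensity undefined")
  wi <- d$dPdt * d$dUdt
  lab <- rep(NA_character_, length(wi))
  ok <- abs(d$dPdt) >= 0.01 * mp & abs(d$dUdt) >= 0.01 * mu
  lab[ok & d$dPdt > 0 & d$dUdt > 0] <- "FCW"
  lab[ok & d$dPdt > 0 & d$dUdt < 0] <- "BCW"
  lab[ok & d$dPdt < 0 & d$dUdt < 0] <- "FEW"
  lab[ok & d$dPdt < 0 & d$dUdt > 0] <- "BEW"
  structure(list(
    time = beat$time, dPdt = d$dPdt, dUdt = d$dUdt, wi = wi,
    quadrant = lab,
    expansion_start = beat$time[which.max(beat$pd)],
    expansion_end = length(beat$time) / beat$fs,
    fs = beat$fs
  ), class = "wia_profile")
}

#' @export
print.wia_profile <- function(x, ...) {
  cat(sprintf("<wia_profile> %d samples @ %g Hz\n", length(x$time), x$fs))
  cat(sprintf("  expansion phase: %.3f - %.3f s\n",
              x$expansion_start, x$expansion_end))
  print(table(factor(x$quadrant, levels = c("FCW", "BCW", "FEW", "BEW")),
              useNA = "ifany"))
  invisible(x)
}

#' @export
plot.wia_profile <- function(x, ...) {
  cols <- c(FCW = "firebrick", BCW = "orange", FEW = "steelblue",
            BEW = "darkgreen")
  graphics::plot(x$time, x$wi, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = expression(WI ~ (W ~ m^-2 ~ s^-2)), ...)
  for (q in names(cols)) {
    i <- which(x$quadrant == q)
    if (length(i)) graphics::points(x$time[i], x$wi[i], col = cols[q],
                                    pch = 16, cex = 0.4)
  }
  graphics::abline(v = x$expansion_start, lty = 2)
  graphics::legend("topright", names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Extract the four canonical wave peaks and the suction-wave timing
#'
#' Peak amplitudes are the maximum |WI| over samples carrying each quadrant
#' label, with temporal gating: the compression waves (FCW, BCW) are
#' searched from cycle start to the expansion onset, the expansion waves
#' (FEW, BEW) within the expansion phase. Amplitudes are reported in the
#' conventional unit 10 kW.m-2.s-2 (raw W.m-2.s-2 divided by 1e4). The
#' relative suction-wave timing is
#' \code{tBEW_peak = (t_BEW - expansion_start)/(expansion_end -
#' expansion_start)}, a heart-rate-independent fraction of the expansion
#' phase. A missing backward expansion wave raises a classed error rather
#' than silently reporting zero.
#'
#' @param profile a \code{\link{wia_profile}}.
#' @return An object of class \code{wave_peaks} with peak amplitudes,
#'   peak times, \code{tBEW_peak} and \code{accel_energy_fraction}.
#' @export
extract_peaks <- function(profile) {
  stopifnot(inherits(profile, "wia_profile"))
  es <- profile$expansion_start
  pre <- profile$time < es
  expa <- profile$time >= es
  pick <- function(wave, mask) {
    i <- which(profile$quadrant == wave & mask)
    if (!length(i)) return(list(amp = NA_real_, t = NA_real_))
    j <- i[which.max(abs(profile$wi[i]))]
    list(amp = abs(profile$wi[j]) / PEAK_UNIT, t = profile$time[j])
  }
  fcw <- pick("FCW", pre); bcw <- pick("BCW", pre)
  few <- pick("FEW", expa); bew <- pick("BEW", expa)
  if (is.na(bew$amp))
    stop_corowia("corowia_missing_wave",
                 "no backward expansion wave found in the expansion phase")
  structure(list(
    FCW_peak = fcw$amp, BCW_peak = bcw$amp,
    FEW_peak = few$amp, BEW_peak = bew$amp,
    t_FCW = fcw$t, t_BCW = bcw$t, t_FEW = few$t, t_BEW = bew$t,
    tBEW_peak = (bew$t - es) / (profile$expansion_end - es),
    accel_energy_fraction = accel_energy_fraction(profile)
  ), class = "wave_peaks")
}

#' @export
print.wave_peaks <- function(x, digits = 3, ...) {
  cat("<wave_peaks> amplitudes in 10 kW.m-2.s-2\n")
  f <- function(v) formatC(v, digits = digits, format = "fg")
  cat(sprintf("  FCW %s (t=%.3f)  BCW %s (t=%.3f)\n",
              f(x$FCW_peak), x$t_FCW, f(x$BCW_peak), x$t_BCW))
  cat(sprintf("  FEW %s (t=%.3f)  BEW %s (t=%.3f)\n",
              f(x$FEW_peak), x$t_FEW, f(x$BEW_peak), x$t_BEW))
  cat(sprintf("  tBEW_peak %s of expansion, accelerating energy fraction %s\n",
              f(x$tBEW_peak), f(x$accel_energy_fraction)))
  invisible(x)
}

#' Accelerating wave-energy proportion
#'
#' Fraction of the total labeled wave energy carried by the two
#' flow-accelerating waves (FCW and BEW): the trapezoidal integral of |WI|
#' over samples labeled FCW or BEW divided by the integral over all labeled
#' samples. Invariant to joint scaling of both channels.
#'
#' @param profile a \code{\link{wia_profile}}.
#' @return Fraction in [0, 1].
#' @export
accel_energy_fraction <- function(profile) {
  stopifnot(inherits(profile, "wia_profile"))
  labeled <- !is.na(profile$quadrant)
  accel <- labeled & profile$quadrant %in% c("FCW", "BEW")
  aw <- abs(profile$wi)
  # the profile covers one full periodic cycle, so the natural quadrature
  # is the rectangle rule (equivalent to the trapezoid on the wrapped
  # cycle); this also keeps a quadrant's energy independent of where its
  # mask happens to be cut by the array boundary
  dt <- diff(profile$time)
  w <- c(dt, dt[length(dt)])
  den <- sum(w * aw * labeled)
  if (den <= 0)
    stop_corowia("corowia_degenerate_beat",
                 "zero total labeled wave energy")
  sum(w * aw * accel) / den
}
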