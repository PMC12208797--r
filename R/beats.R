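#' Bring all channels onto the pressure sampling grid
#'
#' Velocity is upsampled to the pressure grid by shape-preserving (monotone
#' Hermite) interpolation; pressure is never downsampled, so the bandwidth
#' of dP/dt used by wave-intensity analysis is preserved. A recording
#' already on a common grid is returned unchanged (up to trimming a trailing
#' sample so channel lengths agree).
#'
#' @param rec a \code{\link{vessel_recording}}.
#' @return The recording with all channels at \code{fs_pressure}.
#' @export
resample_to_common_grid <- function(rec) {
  stopifnot(inherits(rec, "vessel_recording"))
  if (rec$fs_pressure < rec$fs_velocity)
    stop_corowia("corowia_format_error",
                 "fs_pressure must be >= fs_velocity")
  if (rec$fs_pressure == rec$fs_velocity) {
    n <- min(length(rec$pa), length(rec$u))
    rec$pa <- rec$pa[seq_len(n)]; rec$pd <- rec$pd[seq_len(n)]
    rec$u <- rec$u[seq_len(n)]
    return(rec)
  }
  t_u <- (seq_along(rec$u) - 1) / rec$fs_velocity
  t_p <- (seq_along(rec$pa) - 1) / rec$fs_pressure
  f <- stats::splinefun(t_u, rec$u, method = "monoH.FC")
  rec$u <- f(pmin(t_p, max(t_u)))
  rec$fs_velocity <- rec$fs_pressure
  rec
}

#' Beat onset index
#'
#' Constructor for a set of beat onsets on the pressure grid with per-beat
#' quality flags, as produced by \code{\link{detect_beats}} or supplied from
#' known ground truth.
#'
#' @param onsets strictly increasing integer sample indices (1-based) of the
#'   diastolic pressure foot; beat \code{i} spans
#'   \code{onsets[i] ... onsets[i+1]-1}.
#' @param fs sampling rate of the pressure grid, Hz.
#' @param flags optional character vector (\code{"ok"}/\code{"rejected"}),
#'   one per beat (length \code{length(onsets) - 1}).
#' @return An object of class \code{beat_index}.
#' @export
beat_index <- function(onsets, fs, flags = NULL) {
  onsets <- as.integer(round(onsets))
  if (length(onsets) < 2L || any(diff(onsets) <= 0))
    stop_corowia("corowia_segmentation_error",
                 "onsets must contain at least two strictly increasing indices")
  n_beats <- length(onsets) - 1L
  if (is.null(flags)) flags <- rep("ok", n_beats)
  if (length(flags) != n_beats)
    stop_corowia("corowia_parameter_error",
                 "flags must have one entry per beat")
  structure(list(onsets = onsets, flags = flags, fs = fs),
            class = "beat_index")
}

#' @export
print.beat_index <- function(x, ...) {
  n <- length(x$onsets) - 1L
  cat(sprintf("<beat_index> %d beats (%d accepted) @ %g Hz\n",
              n, sum(x$flags == "ok"), x$fs))
  invisible(x)
}

#' Detect beat onsets at the diastolic pressure foot
#'
#' Onsets are located as the local pressure minimum preceding the steepest
#' systolic upstroke (dP/dt-threshold-then-minimum search, the standard
#' pulse-foot landmark). Beats whose cycle length deviates by more than 20%
#' from the running median, or falls outside the physiological 0.33-1.5 s
#' band, are flagged \code{"rejected"}.
#'
#' @param pa aortic pressure series, mmHg.
#' @param fs sampling rate, Hz.
#' @return A \code{\link{beat_index}}.
#' @export
detect_beats <- function(pa, fs) {
  n <- length(pa)
  if (n < 11L || diff(range(pa)) < 5)
    stop_corowia("corowia_segmentation_error",
                 "pressure trace is too short or has no pulsatile component")
  ps <- sg_filter(pa, 2, 11, 0, edge = "fit")
  d <- sg_filter(pa, 2, 11, 1, fs = fs, edge = "fit")
  thr <- 0.5 * max(d)
  if (!is.finite(thr) || thr <= 0)
    stop_corowia("corowia_segmentation_error", "no systolic upstroke found")

  runs <- rle(d > thr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(d[seg])])
  }
  # enforce a 0.33 s refractory period between upstrokes
  min_gap <- round(0.33 * fs)
  keep <- integer(0)
  for (c0 in cand) {
    if (!length(keep) || c0 - keep[length(keep)] >= min_gap)
      keep <- c(keep, c0)
  }
  # foot: minimum of the smoothed pressure in the 0.3 s before the upstroke
  back <- round(0.3 * fs)
  onsets <- vapply(keep, function(c0) {
    lo <- max(1L, c0 - back)
    as.integer(lo + which.min(ps[lo:c0]) - 1L)
  }, integer(1))
  onsets <- sort(unique(onsets))
  onsets <- onsets[c(TRUE, diff(onsets) >= min_gap)]
  if (length(onsets) < 2L)
    stop_corowia("corowia_segmentation_error",
                 sprintf("fewer than 2 beat onsets found (%d)", length(onsets)))

  iv <- diff(onsets) / fs
  ref <- if (length(iv) >= 3L)
    stats::runmed(iv, k = min(5L, length(iv) - (1 - length(iv) %% 2L)))
  else rep(stats::median(iv), length(iv))
  flags <- ifelse(iv >= 0.33 & iv <= 1.5 & abs(iv - ref) <= 0.2 * ref,
                  "ok", "rejected")
  beat_index(onsets, fs, flags)
}

#' Select resting and hyperemic analysis windows
#'
#' Operationalises automatic window selection on a continuous recording that
#' spans the adenosine-induced hyperemia transition. The hyperemic window is
#' the contiguous plateau (rolling 10-beat mean of the beat-mean velocity
#' changing by less than \code{plateau_slope} per beat) with the highest mean
#' velocity, ties broken by later onset; the resting window is the
#' lowest-variance \code{rest_span}-second span before the stimulus. Both
#' windows must contain at least \code{min_beats} accepted beats.
#'
#' @param rec a \code{\link{vessel_recording}} with
#'   \code{condition = "continuous"} (or any recording spanning the
#'   transition).
#' @param plateau_slope maximum relative change of the rolling-mean velocity
#'   per beat within a plateau (default 2%).
#' @param rest_span length of the resting window, seconds.
#' @param min_beats minimum accepted beats per window.
#' @return A list of class \code{window_selection} with \code{rest_window}
#'   and \code{hyperemia_window} (start/end seconds) and a \code{method_trace}
#'   text log of the scores used.
#' @export
select_windows <- function(rec, plateau_slope = 0.02, rest_span = 15,
                           min_beats = 8L) {
  rec <- resample_to_common_grid(rec)
  beats <- detect_beats(rec$pa, rec$fs_pressure)
  on <- beats$onsets
  nb <- length(on) - 1L
  ubar <- vapply(seq_len(nb), function(i)
    mean(rec$u[on[i]:(on[i + 1L] - 1L)]), numeric(1))
  tstart <- (on[-length(on)] - 1) / rec$fs_pressure
  tend <- (on[-1L] - 1) / rec$fs_pressure
  okb <- beats$flags == "ok"

  k <- 10L
  roll <- stats::filter(ubar, rep(1 / k, k), sides = 1)
  roll <- as.numeric(roll)
  slope <- c(NA, diff(roll) / roll[-length(roll)])
  baseline <- mean(ubar[okb][seq_len(min(10L, sum(okb)))])

  plateau <- !is.na(slope) & abs(slope) < plateau_slope
  r <- rle(plateau)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
  spans <- data.frame(start = rs[r$values], end = re[r$values])
  if (nrow(spans)) {
    spans$n_ok <- vapply(seq_len(nrow(spans)), function(i)
      sum(okb[spans$start[i]:spans$end[i]]), numeric(1))
    spans$mean <- vapply(seq_len(nrow(spans)), function(i)
      mean(ubar[spans$start[i]:spans$end[i]]), numeric(1))
    spans <- spans[spans$n_ok >= min_beats & spans$mean > 1.15 * baseline, ,
                   drop = FALSE]
  }
  trace <- sprintf("baseline velocity %.2f cm/s over first accepted beats; %d candidate plateau(s)",
                   baseline, nrow(spans))
  if (!nrow(spans))
    stop_corowia("corowia_selection_error",
                 paste("no hyperemic plateau found;", trace))
  best <- max(spans$mean)
  spans <- spans[spans$mean >= best - 1e-9, , drop = FALSE]
  sel <- spans[which.max(spans$start), ]   # tie -> later onset
  # the trailing rolling mean flags the plateau late; walk the start back
  # over beats already at the plateau level to the true onset
  s0 <- sel$start
  while (s0 > 1 && abs(ubar[s0 - 1L] - sel$mean) < 0.03 * sel$mean)
    s0 <- s0 - 1L
  hyp <- c(tstart[s0], tend[sel$end])
  trace <- c(trace, sprintf("hyperemia plateau beats %d-%d, mean %.2f cm/s",
                            sel$start, sel$end, sel$mean))

  # resting window: lowest-variance span before the rise toward the plateau
  pre <- which(tend <= hyp[1] & roll <= 1.1 * baseline & okb)
  if (length(pre) < min_beats)
    stop_corowia("corowia_selection_error",
                 "insufficient pre-stimulus beats for a resting window")
  best_var <- Inf; rest <- NULL
  for (i in pre) {
    j <- pre[tend[pre] <= tstart[i] + rest_span & pre >= i]
    if (length(j) >= min_beats) {
      v <- stats::var(ubar[j])
      if (v < best_var) { best_var <- v; rest <- c(tstart[i], tend[max(j)]) }
    }
  }
  if (is.null(rest)) {  # recording shorter than rest_span: use all pre beats
    rest <- c(tstart[pre[1]], tend[pre[length(pre)]])
    best_var <- stats::var(ubar[pre])
  }
  trace <- c(trace, sprintf("rest window variance %.4f over [%.1f, %.1f] s",
                            best_var, rest[1], rest[2]))
  structure(list(rest_window = rest, hyperemia_window = hyp,
                 method_trace = trace, beats = beats),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat("<window_selection>\n")
  cat(sprintf("  rest:      %.2f - %.2f s\n", x$rest_window[1], x$rest_window[2]))
  cat(sprintf("  hyperemia: %.2f - %.2f s\n",
              x$hyperemia_window[1], x$hyperemia_window[2]))
  cat("  trace:\n"); for (l in x$method_trace) cat("   ", l, "\n")
  invisible(x)
}

#' Representative ensemble-averaged beat
#'
#' Constructor for a single cardiac cycle of Pa, Pd and U on one uniform
#' time grid.
#'
#' @param time uniform time grid starting at 0, seconds.
#' @param pa,pd pressures, mmHg.
#' @param u velocity, cm/s.
#' @param fs sampling rate of the grid, Hz.
#' @param n_beats_averaged number of beats entering the average.
#' @return An object of class \code{ensemble_beat}.
#' @export
ensemble_beat <- function(time, pa, pd, u, fs, n_beats_averaged = 1L) {
  stopifnot(length(time) == length(pa), length(pa) == length(pd),
            length(pd) == length(u))
  structure(list(time = time, pa = pa, pd = pd, u = u, fs = fs,
                 n_beats_averaged = n_beats_averaged),
            class = "ensemble_beat")
}

#' @export
print.ensemble_beat <- function(x, ...) {
  cat(sprintf("<ensemble_beat> %d samples @ %g Hz (cycle %.3f s), %d beats averaged\n",
              length(x$time), x$fs, length(x$time) / x$fs, x$n_beats_averaged))
  cat(sprintf("  <Pa> %.1f  <Pd> %.1f mmHg   <U> %.1f cm/s\n",
              time_average(x, "pa"), time_average(x, "pd"), time_average(x, "u")))
  invisible(x)
}

#' @export
plot.ensemble_beat <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$pa, type = "l", xlab = "time (s)",
                 ylab = "P (mmHg)", ylim = range(x$pa, x$pd), ...)
  graphics::lines(x$time, x$pd, col = 2)
  graphics::legend("topright", c("Pa", "Pd"), col = 1:2, lty = 1, bty = "n")
  graphics::plot(x$time, x$u, type = "l", xlab = "time (s)",
                 ylab = "U (cm/s)", ...)
  invisible(x)
}

#' Ensemble-average beats into a representative cardiac cycle
#'
#' Accepted beats (optionally restricted to an analysis window) are linearly
#' time-normalised to the median cycle length and averaged samplewise per
#' channel. At least 8 accepted beats are required, reflecting standard
#' practice for coronary wave-intensity analysis.
#'
#' @param rec a \code{\link{vessel_recording}} (resampled internally to the
#'   pressure grid if needed).
#' @param beats a \code{\link{beat_index}}; detected automatically when
#'   omitted.
#' @param window optional \code{c(start, end)} in seconds; only beats fully
#'   inside are used.
#' @param min_beats minimum number of accepted beats (default 8).
#' @return An \code{\link{ensemble_beat}}.
#' @export
ensemble_average <- function(rec, beats = NULL, window = NULL, min_beats = 8L) {
  rec <- resample_to_common_grid(rec)
  fs <- rec$fs_pressure
  if (is.null(beats)) beats <- detect_beats(rec$pa, fs)
  on <- beats$onsets
  nb <- length(on) - 1L
  sel <- which(beats$flags == "ok")
  if (!is.null(window)) {
    t0 <- (on[-length(on)] - 1) / fs
    t1 <- (on[-1L] - 1) / fs
    sel <- sel[t0[sel] >= window[1] - 1e-9 & t1[sel] <= window[2] + 1e-9]
  }
  sel <- sel[on[sel + 1L] - 1L <= length(rec$pa)]
  if (length(sel) < min_beats)
    stop_corowia("corowia_insufficient_beats",
                 sprintf("only %d accepted beats available; %d required",
                         length(sel), min_beats),
                 n_beats = length(sel))
  L <- diff(on)
  n_out <- as.integer(round(stats::median(L[sel])))
  grid_out <- (seq_len(n_out) - 1) / n_out
  avg <- function(x) {
    acc <- numeric(n_out)
    for (i in sel) {
      idx <- on[i]:(on[i + 1L] - 1L)
      pos <- (seq_along(idx) - 1) / length(idx)
      acc <- acc + stats::approx(pos, x[idx], xout = grid_out, rule = 2)$y
    }
    acc / length(sel)
  }
  ensemble_beat(time = (seq_len(n_out) - 1) / fs,
                pa = avg(rec$pa), pd = avg(rec$pd), u = avg(rec$u),
                fs = fs, n_beats_averaged = length(sel))
}
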