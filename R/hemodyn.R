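#' Time-average of an ensemble-beat channel
#'
#' Mean over the full representative cycle, computed as the trapezoidal
#' integral divided by the spanned time, which remains correct on
#' non-uniform grids.
#'
#' @param beat an \code{\link{ensemble_beat}}.
#' @param channel one of \code{"pa"}, \code{"pd"}, \code{"u"}.
#' @return Scalar time-average (mmHg or cm/s).
#' @export
time_average <- function(beat, channel = c("pa", "pd", "u")) {
  channel <- match.arg(channel)
  x <- beat[[channel]]
  t <- beat$time
  if (length(x) < 2L)
    stop_corowia("corowia_parameter_error", "empty or degenerate beat")
  trapz(t, x) / (t[length(t)] - t[1])
}

#' Conventional pressure-velocity indices for one vessel state
#'
#' Computes the full set of resting/hyperemic indices from the two
#' representative beats of a vessel in one phase (pre- or post-PCI):
#' \itemize{
#'  \item \code{FFR = <Pd_hyp>/<Pa_hyp>} (fractional flow reserve)
#'  \item \code{CFVR = <U_hyp>/<U_rest>} (coronary flow velocity reserve)
#'  \item \code{hSR = (<Pa_hyp>-<Pd_hyp>)/<U_hyp>} (hyperemic stenosis
#'    resistance), \code{deltaP = <Pa_hyp>-<Pd_hyp>}
#'  \item \code{bMR = <Pd_rest>/<U_rest>}, \code{hMR = <Pd_hyp>/<U_hyp>}
#'    (basal/hyperemic microvascular resistance)
#'  \item \code{MRR = (CFVR/FFR) (<Pa_rest>/<Pa_hyp>)} (microvascular
#'    resistance reserve), \code{RRR = bMR/hMR} (resistive reserve ratio)
#' }
#' Averages are taken over the ensemble beat so that the conventional
#' indices and the wave-intensity analysis share one representative cycle.
#'
#' @param rest,hyp \code{\link{ensemble_beat}}s of the same vessel/phase at
#'   rest and during hyperemia.
#' @param vessel_id,phase optional labels.
#' @return An object of class \code{hemo_indices}.
#' @export
compute_indices <- function(rest, hyp, vessel_id = NULL, phase = NULL) {
  m <- list(
    pa_r = time_average(rest, "pa"), pd_r = time_average(rest, "pd"),
    u_r = time_average(rest, "u"),
    pa_h = time_average(hyp, "pa"), pd_h = time_average(hyp, "pd"),
    u_h = time_average(hyp, "u")
  )
  if (m$u_r <= 0 || m$u_h <= 0)
    stop_corowia("corowia_degenerate_flow",
                 "non-positive mean velocity; indices undefined")
  if (m$pa_r <= 0 || m$pa_h <= 0)
    stop_corowia("corowia_degenerate_pressure",
                 "non-positive mean aortic pressure; indices undefined")
  ffr <- m$pd_h / m$pa_h
  cfvr <- m$u_h / m$u_r
  structure(list(
    vessel_id = vessel_id, phase = phase,
    bAPV = m$u_r, hAPV = m$u_h,
    Pa_rest_mean = m$pa_r, Pa_hyp_mean = m$pa_h,
    Pd_rest_mean = m$pd_r, Pd_hyp_mean = m$pd_h,
    FFR = ffr, CFVR = cfvr,
    hSR = (m$pa_h - m$pd_h) / m$u_h,
    deltaP = m$pa_h - m$pd_h,
    bMR = m$pd_r / m$u_r, hMR = m$pd_h / m$u_h,
    MRR = (cfvr / ffr) * (m$pa_r / m$pa_h),
    RRR = (m$pd_r / m$u_r) / (m$pd_h / m$u_h)
  ), class = "hemo_indices")
}

#' @export
print.hemo_indices <- function(x, digits = 3, ...) {
  cat(sprintf("<hemo_indices>%s%s\n",
              if (!is.null(x$vessel_id)) paste0(" ", x$vessel_id) else "",
              if (!is.null(x$phase)) paste0(" [", x$phase, "-PCI]") else ""))
  f <- function(v) formatC(v, digits = digits, format = "fg")
  cat(sprintf("  FFR %s  CFVR %s  hSR %s mmHg.cm-1.s  deltaP %s mmHg\n",
              f(x$FFR), f(x$CFVR), f(x$hSR), f(x$deltaP)))
  cat(sprintf("  bMR %s  hMR %s mmHg.cm-1.s  MRR %s  RRR %s\n",
              f(x$bMR), f(x$hMR), f(x$MRR), f(x$RRR)))
  cat(sprintf("  bAPV %s  hAPV %s cm/s\n", f(x$bAPV), f(x$hAPV)))
  invisible(x)
}

#' @export
as.data.frame.hemo_indices <- function(x, ...) {
  flds <- c("bAPV", "hAPV", "Pa_rest_mean", "Pa_hyp_mean", "Pd_rest_mean",
            "Pd_hyp_mean", "FFR", "CFVR", "hSR", "deltaP", "bMR", "hMR",
            "MRR", "RRR")
  d <- as.data.frame(x[flds], stringsAsFactors = FALSE)
  d <- cbind(data.frame(vessel_id = x$vessel_id %||% NA_character_,
                        phase = x$phase %||% NA_character_,
                        stringsAsFactors = FALSE), d)
  d
}

#' Stratify a vessel by its post-PCI FFR and hSR
#'
#' Applies the conventional 0.80 cut-offs: \code{"concordant"} when
#' FFR > 0.8 with hSR < 0.8, \code{"discordant"} (residual low FFR despite
#' normalised stenosis resistance) when FFR <= 0.8 with hSR < 0.8, and
#' \code{"abnormal_hSR"} when hSR >= 0.8. The boundary conventions follow
#' the printed definitions: abnormal FFR uses \code{<= 0.8}, normal hSR is
#' strict \code{< 0.8}.
#'
#' @param post_indices a \code{\link{hemo_indices}} from the post-PCI state.
#' @return \code{"concordant"}, \code{"discordant"} or \code{"abnormal_hSR"}.
#' @export
classify_vessel <- function(post_indices) {
  stopifnot(inherits(post_indices, "hemo_indices"))
  if (post_indices$hSR >= 0.8) return("abnormal_hSR")
  if (post_indices$FFR > 0.8) "concordant" else "discordant"
}
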