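#' Parameters of a synthetic coronary beat
#'
#' Describes one vessel state (a condition x phase cell) for the waveform
#' generator. Pressures follow a raised-cosine systolic upstroke with an
#' exponential diastolic decay; velocity has a small systolic lobe and a
#' dominant diastolic lobe whose acceleration peak -- the substrate of the
#' backward expansion (suction) wave -- is placed at a controllable position
#' within the expansion phase. The distal pressure is derived from the
#' aortic pressure by a translesional drop proportional to velocity,
#' \code{Pd(t) = Pa(t) - stenosis_resistance * U(t)}, before sensor noise.
#'
#' The time-averaged velocity is set by the total resistance,
#' \code{<U> = <Pa> / (microvascular_resistance + stenosis_resistance)},
#' unless \code{u_mean} pins it explicitly. With resistance-driven scaling
#' the noiseless ground truth satisfies \code{FFR = hMR / (hMR + hSR)}
#' exactly, with \code{hSR = stenosis_resistance} and
#' \code{hMR = microvascular_resistance}.
#'
#' @param heart_rate beats per minute, in [40, 140].
#' @param p_sys,p_dia systolic peak and end-diastolic aortic pressure, mmHg;
#'   \code{p_sys > p_dia > 0}.
#' @param systole_fraction fraction of the cycle before the onset of the
#'   pressure decay (position of the aortic peak), in (0, 1).
#' @param stenosis_resistance translesional resistance, mmHg.cm^-1.s; >= 0.
#' @param microvascular_resistance distal bed resistance, mmHg.cm^-1.s; >= 0.
#'   The sum of the two resistances must be positive unless \code{u_mean}
#'   is supplied.
#' @param suction_delay_frac target position of the diastolic velocity
#'   acceleration peak within the expansion phase (aortic peak to
#'   end-diastole), in [0, 1).
#' @param suction_gain dimensionless amplitude of the diastolic (suction)
#'   velocity lobe relative to the template scale; >= 0.
#' @param noise_sd_p,noise_sd_u additive white Gaussian sensor noise,
#'   mmHg and cm/s.
#' @param fs_pressure,fs_velocity sampling rates in Hz, each one of
#'   100, 120 or 200.
#' @param hr_jitter_frac standard deviation of the per-beat cycle-length
#'   multiplier (beat-to-beat variability); 0 gives identical beats.
#' @param u_mean optional target time-averaged velocity in cm/s, overriding
#'   resistance-driven velocity scaling.
#' @param seed integer seed consumed by the generator.
#' @return An object of class \code{beat_params}.
#' @export
beat_params <- function(heart_rate = 70, p_sys = 120, p_dia = 70,
                        systole_fraction = 0.35,
                        stenosis_resistance = 0.5,
                        microvascular_resistance = 2,
                        suction_delay_frac = 0.2,
                        suction_gain = 1,
                        noise_sd_p = 0, noise_sd_u = 0,
                        fs_pressure = 200, fs_velocity = 100,
                        hr_jitter_frac = 0,
                        u_mean = NULL,
                        seed = 1L) {
  p <- structure(list(
    heart_rate = heart_rate, p_sys = p_sys, p_dia = p_dia,
    systole_fraction = systole_fraction,
    stenosis_resistance = stenosis_resistance,
    microvascular_resistance = microvascular_resistance,
    suction_delay_frac = suction_delay_frac, suction_gain = suction_gain,
    noise_sd_p = noise_sd_p, noise_sd_u = noise_sd_u,
    fs_pressure = fs_pressure, fs_velocity = fs_velocity,
    hr_jitter_frac = hr_jitter_frac,
    u_mean = u_mean,
    seed = as.integer(seed)
  ), class = "beat_params")
  validate_beat_params(p)
}

validate_beat_params <- function(p) {
  chk <- function(cond, msg)
    if (!isTRUE(cond)) stop_corowia("corowia_parameter_error", msg)
  chk(is.numeric(p$p_sys) && is.numeric(p$p_dia) && p$p_sys > p$p_dia,
      "p_sys must exceed p_dia")
  chk(p$p_dia > 0, "p_dia must be > 0")
  chk(p$systole_fraction > 0 && p$systole_fraction < 1,
      "systole_fraction must lie in (0, 1)")
  chk(p$heart_rate >= 40 && p$heart_rate <= 140,
      "heart_rate must lie in [40, 140] beats/min")
  chk(p$stenosis_resistance >= 0, "stenosis_resistance must be >= 0")
  chk(p$microvascular_resistance >= 0, "microvascular_resistance must be >= 0")
  chk(p$suction_delay_frac >= 0 && p$suction_delay_frac < 1,
      "suction_delay_frac must lie in [0, 1)")
  chk(p$suction_gain >= 0, "suction_gain must be >= 0")
  chk(p$noise_sd_p >= 0 && p$noise_sd_u >= 0, "noise sd must be >= 0")
  chk(p$fs_pressure %in% c(100, 120, 200),
      "fs_pressure must be one of 100, 120, 200 Hz")
  chk(p$fs_velocity %in% c(100, 120, 200),
      "fs_velocity must be one of 100, 120, 200 Hz")
  chk(p$hr_jitter_frac >= 0 && p$hr_jitter_frac < 0.2,
      "hr_jitter_frac must lie in [0, 0.2)")
  if (is.null(p$u_mean))
    chk(p$stenosis_resistance + p$microvascular_resistance > 0,
        "stenosis_resistance + microvascular_resistance must be > 0 when u_mean is not given")
  else chk(p$u_mean > 0, "u_mean must be > 0")
  p
}

#' @export
print.beat_params <- function(x, ...) {
  cat("Synthetic beat parameters\n")
  cat(sprintf("  HR %g bpm, Pa %g/%g mmHg, systole fraction %g\n",
              x$heart_rate, x$p_sys, x$p_dia, x$systole_fraction))
  cat(sprintf("  stenosis R %g, microvascular R %g mmHg.cm-1.s\n",
              x$stenosis_resistance, x$microvascular_resistance))
  cat(sprintf("  suction delay %g of expansion, gain %g\n",
              x$suction_delay_frac, x$suction_gain))
  cat(sprintf("  noise sd %g mmHg / %g cm/s, fs %g/%g Hz, seed %d\n",
              x$noise_sd_p, x$noise_sd_u, x$fs_pressure, x$fs_velocity, x$seed))
  invisible(x)
}

#' Specification of a synthetic study cohort
#'
#' Defines the stated world for a pre/post-PCI coronary cohort with a
#' concordant group (post-PCI FFR > 0.8, hSR < 0.8) and a discordant group
#' (residual FFR <= 0.8 despite hSR < 0.8). Group-level means of the
#' resistances, suction timing and suction gain default to the published
#' post-PCI group characteristics of such cohorts (concordant hSR ~0.21,
#' discordant ~0.52 mmHg.cm^-1.s; matched hyperemic velocity near 48 cm/s;
#' discordant suction delayed by ~0.09 of the expansion phase and ~35%
#' weaker). Positive skewed quantities are drawn log-normally.
#'
#' @param n_concordant,n_discordant group sizes; total must be >= 2.
#' @param n_beats beats per generated recording.
#' @param noise_sd_p,noise_sd_u sensor noise levels (mmHg, cm/s).
#' @param hr_jitter_frac beat-to-beat cycle-length variability.
#' @param hyperemia_velocity_multiplier optional fixed hyperemic/basal
#'   velocity ratio (> 1). When given, hyperemic recordings keep the resting
#'   resistances and scale velocity directly, so the true CFVR equals the
#'   multiplier by construction. Default \code{NULL}: hyperemia is
#'   resistance-driven (hMR < bMR draws).
#' @param groups optional list overriding the per-group distribution table
#'   (advanced use; see the package vignette).
#' @param seed integer master seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_concordant = 53, n_discordant = 10,
                        n_beats = 16, noise_sd_p = 1, noise_sd_u = 1,
                        hr_jitter_frac = 0.02,
                        hyperemia_velocity_multiplier = NULL,
                        groups = NULL, seed = 1L) {
  if (n_concordant + n_discordant < 2)
    stop_corowia("corowia_parameter_error",
                 "n_concordant + n_discordant must be >= 2")
  if (!is.null(hyperemia_velocity_multiplier) &&
      hyperemia_velocity_multiplier <= 1)
    stop_corowia("corowia_parameter_error",
                 "hyperemia_velocity_multiplier must be > 1")
  structure(list(
    n_concordant = n_concordant, n_discordant = n_discordant,
    n_beats = n_beats, noise_sd_p = noise_sd_p, noise_sd_u = noise_sd_u,
    hr_jitter_frac = hr_jitter_frac,
    hyperemia_velocity_multiplier = hyperemia_velocity_multiplier,
    groups = if (is.null(groups)) default_cohort_groups() else groups,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Per-group stated world: (mean, sd) pairs per phase x condition.
# Resistances in mmHg.cm-1.s, delays as fraction of the expansion phase.
default_cohort_groups <- function() {
  list(
    concordant = list(
      hSR_pre = c(1.7, 1.5),  hMR_pre = c(2.48, 1.0), bMR_pre = c(4.87, 2.0),
      hSR_post = c(0.21, 0.11), hMR_post = c(1.84, 0.75), bMR_post = c(5.0, 2.0),
      delay = list(pre_rest = c(0.23, 0.10), pre_hyp = c(0.28, 0.10),
                   post_rest = c(0.17, 0.05), post_hyp = c(0.20, 0.06)),
      gain = list(pre_rest = c(0.8, 0.25), pre_hyp = c(0.9, 0.3),
                  post_rest = c(0.85, 0.25), post_hyp = c(1.0, 0.35))
    ),
    discordant = list(
      hSR_pre = c(1.55, 1.29), hMR_pre = c(2.13, 0.68), bMR_pre = c(4.99, 2.0),
      hSR_post = c(0.52, 0.17), hMR_post = c(1.48, 0.53), bMR_post = c(4.3, 1.35),
      delay = list(pre_rest = c(0.20, 0.13), pre_hyp = c(0.34, 0.13),
                   post_rest = c(0.18, 0.08), post_hyp = c(0.29, 0.09)),
      gain = list(pre_rest = c(0.8, 0.25), pre_hyp = c(0.9, 0.3),
                  post_rest = c(0.85, 0.25), post_hyp = c(0.65, 0.20))
    )
  )
}
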