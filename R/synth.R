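# Waveform template -----------------------------------------------------
#
# One noiseless beat is a pair of closures Pa(t), U(t) on [0, T), T = 60/HR.
# Pressure: raised-cosine systolic upstroke peaking at tp = systole_fraction*T,
# then an exponential decay back to p_dia at T (decay constant 3 per expansion
# span, a realistic aortic diastolic time constant).
# Velocity: baseline + small systolic lobe (ends before the aortic peak, so a
# decelerating-flow/rising-pressure interval exists) + dominant diastolic lobe
# whose raised-cosine rise is centred so its acceleration peak falls at
# suction_delay_frac of the expansion phase. Distal pressure is
# Pd = Pa - stenosis_resistance * U, pointwise.

raised_lobe <- function(t, t0, wr, t1) {
  y <- numeric(length(t))
  i <- t >= t0 & t < t0 + wr
  if (wr > 0) y[i] <- 0.5 * (1 - cos(pi * (t[i] - t0) / wr))
  wf <- t1 - (t0 + wr)
  j <- t >= t0 + wr & t <= t1
  if (wf > 0) y[j] <- 0.5 * (1 + cos(pi * (t[j] - t0 - wr) / wf))
  y
}

beat_template <- function(params) {
  p <- params
  T0 <- 60 / p$heart_rate
  tp <- p$systole_fraction * T0
  S <- T0 - tp
  kappa <- 3
  dp <- p$p_sys - p$p_dia

  pa_fun <- function(t) {
    tm <- t %% T0
    y <- numeric(length(tm))
    i <- tm < tp
    y[i] <- p$p_dia + dp * 0.5 * (1 - cos(pi * tm[i] / tp))
    s <- tm[!i] - tp
    y[!i] <- p$p_dia + dp * (exp(-kappa * s / S) - exp(-kappa)) / (1 - exp(-kappa))
    y
  }

  # diastolic (suction) lobe geometry: acceleration peak at tb = tp + f*S
  f <- p$suction_delay_frac
  w <- S * max(min(0.2, 1.8 * f, 1.6 * (1 - f)), 0.05)
  t0d <- max(tp + f * S - w / 2, tp)

  # phasicity damping with stenosis severity: a severe lesion flattens the
  # distal velocity envelope; the cubic law keeps the translesional drop
  # Rs*U(t) below the instantaneous aortic pressure across the admissible
  # parameter space (so Pd stays positive by construction)
  rtot <- p$microvascular_resistance + p$stenosis_resistance
  damp <- if (rtot > 0) (p$microvascular_resistance / rtot)^3 else 1

  u_shape <- function(t) {
    tm <- t %% T0
    0.5 + damp *
      (0.35 * raised_lobe(tm, 0.10 * tp, 0.45 * tp, 0.95 * tp) +
       p$suction_gain * raised_lobe(tm, t0d, w, T0))
  }

  # scale the shape so <U> matches the resistance relation (or u_mean)
  nf <- 4096L
  tg <- (seq_len(nf) - 1) / nf * T0
  mean_pa <- mean(pa_fun(tg))
  mean_shape <- mean(u_shape(tg))
  lambda <- if (!is.null(p$u_mean)) p$u_mean / mean_shape
  else mean_pa / ((p$microvascular_resistance + p$stenosis_resistance) * mean_shape)

  u_fun <- function(t) lambda * u_shape(t)
  pd_fun <- function(t) pa_fun(t) - p$stenosis_resistance * u_fun(t)
  mean_u <- lambda * mean_shape
  mean_pd <- mean_pa - p$stenosis_resistance * mean_u

  list(pa = pa_fun, u = u_fun, pd = pd_fun,
       period = T0, t_peak = tp, expansion = S,
       mean_pa = mean_pa, mean_pd = mean_pd, mean_u = mean_u)
}

# Evaluate a (possibly per-beat) template train on a uniform grid.
# periods: actual per-beat cycle lengths; each beat's template is evaluated
# at local time linearly rescaled to its natural period (time dilation).
sample_train <- function(fun_list, natural, periods, fs, total) {
  n <- floor(total * fs + 1e-9)
  tt <- (seq_len(n) - 1) / fs
  onsets <- c(0, cumsum(periods))
  b <- findInterval(tt, onsets, rightmost.closed = FALSE)
  b[b > length(periods)] <- length(periods)
  s <- (tt - onsets[b]) / periods[b] * natural[b]
  y <- numeric(n)
  for (k in unique(b)) {
    i <- b == k
    y[i] <- fun_list[[k]](s[i])
  }
  y
}

#' Generate a synthetic beat train
#'
#' Produces a multi-beat recording of aortic pressure, distal pressure and
#' Doppler velocity from one parameter set. Beats are identical up to the
#' optional cycle-length jitter; independent Gaussian sensor noise is added
#' per sample and channel. Fully reproducible under \code{params$seed}.
#'
#' @param params a \code{\link{beat_params}} object.
#' @param n_beats number of beats (>= 1).
#' @param vessel_id,phase,condition labels carried into the recording.
#' @return A \code{\link{vessel_recording}}; attribute \code{"truth"} holds
#'   the generating parameters, the noiseless channel means, the true beat
#'   onset times (s) and per-beat periods.
#' @examples
#' rec <- synth_beat(beat_params(heart_rate = 60, seed = 7), n_beats = 3)
#' rec
#' @export
synth_beat <- function(params, n_beats, vessel_id = "V1",
                       phase = "pre", condition = "rest") {
  validate_beat_params(params)
  if (!is.numeric(n_beats) || n_beats < 1)
    stop_corowia("corowia_parameter_error", "n_beats must be >= 1")
  n_beats <- as.integer(n_beats)
  set.seed(params$seed)

  tmpl <- beat_template(params)
  T0 <- tmpl$period
  mult <- if (params$hr_jitter_frac > 0)
    pmin(pmax(stats::rnorm(n_beats, 1, params$hr_jitter_frac), 0.85), 1.15)
  else rep(1, n_beats)
  periods <- T0 * mult
  total <- sum(periods)

  natural <- rep(T0, n_beats)
  pa_list <- lapply(seq_len(n_beats), function(i) tmpl$pa)
  u_list <- lapply(seq_len(n_beats), function(i) tmpl$u)
  pd_list <- lapply(seq_len(n_beats), function(i) tmpl$pd)

  pa <- sample_train(pa_list, natural, periods, params$fs_pressure, total)
  pd <- sample_train(pd_list, natural, periods, params$fs_pressure, total)
  u <- sample_train(u_list, natural, periods, params$fs_velocity, total)

  if (params$noise_sd_p > 0) {
    # clamp at zero: a pressure sensor does not report negative absolute
    # pressure, and the validator rejects negative samples
    pa <- pmax(pa + stats::rnorm(length(pa), 0, params$noise_sd_p), 0)
    pd <- pmax(pd + stats::rnorm(length(pd), 0, params$noise_sd_p), 0)
  }
  if (params$noise_sd_u > 0)
    u <- u + stats::rnorm(length(u), 0, params$noise_sd_u)

  rec <- vessel_recording(pa, pd, u, params$fs_pressure, params$fs_velocity,
                          vessel_id = vessel_id, phase = phase,
                          condition = condition)
  attr(rec, "truth") <- list(
    params = params,
    onsets = c(0, cumsum(periods))[seq_len(n_beats)],
    periods = periods,
    mean_pa = tmpl$mean_pa, mean_pd = tmpl$mean_pd, mean_u = tmpl$mean_u,
    t_peak = tmpl$t_peak
  )
  rec
}

#' Generate the four recordings of one vessel with ground truth
#'
#' Builds the rest/hyperemia pair for the pre-PCI and post-PCI states of a
#' single vessel and tabulates the analytic ground-truth indices computed on
#' noiseless time-averages, so that downstream recovery error isolates
#' pipeline error from generation error.
#'
#' @param pre_rest,pre_hyp,post_rest,post_hyp \code{\link{beat_params}} for
#'   each condition x phase cell. Hyperemic parameters must yield a higher
#'   mean velocity than the matching resting parameters.
#' @param n_beats beats per recording.
#' @param vessel_id identifier shared by the four recordings.
#' @return List with \code{recordings} (named list \code{pre_rest},
#'   \code{pre_hyp}, \code{post_rest}, \code{post_hyp}) and \code{truth}
#'   (data frame, one row per phase with FFR, CFVR, hSR, bMR, hMR, deltaP,
#'   bAPV, hAPV and the configured suction delays).
#' @export
synth_vessel <- function(pre_rest, pre_hyp, post_rest, post_hyp,
                         n_beats = 16, vessel_id = "V1") {
  cells <- list(pre_rest = pre_rest, pre_hyp = pre_hyp,
                post_rest = post_rest, post_hyp = post_hyp)
  tmpl <- lapply(cells, beat_template)
  for (ph in c("pre", "post")) {
    if (tmpl[[paste0(ph, "_hyp")]]$mean_u <= tmpl[[paste0(ph, "_rest")]]$mean_u)
      stop_corowia("corowia_parameter_error",
                   sprintf("%s-PCI hyperemic mean velocity must exceed the resting one (multiplier > 1)", ph))
  }
  recs <- list(
    pre_rest = synth_beat(pre_rest, n_beats, vessel_id, "pre", "rest"),
    pre_hyp = synth_beat(pre_hyp, n_beats, vessel_id, "pre", "hyperemia"),
    post_rest = synth_beat(post_rest, n_beats, vessel_id, "post", "rest"),
    post_hyp = synth_beat(post_hyp, n_beats, vessel_id, "post", "hyperemia")
  )
  truth_row <- function(ph) {
    r <- tmpl[[paste0(ph, "_rest")]]
    h <- tmpl[[paste0(ph, "_hyp")]]
    data.frame(
      vessel_id = vessel_id, phase = ph,
      FFR = h$mean_pd / h$mean_pa,
      CFVR = h$mean_u / r$mean_u,
      hSR = (h$mean_pa - h$mean_pd) / h$mean_u,
      deltaP = h$mean_pa - h$mean_pd,
      bMR = r$mean_pd / r$mean_u,
      hMR = h$mean_pd / h$mean_u,
      bAPV = r$mean_u, hAPV = h$mean_u,
      suction_delay_rest = cells[[paste0(ph, "_rest")]]$suction_delay_frac,
      suction_delay_hyp = cells[[paste0(ph, "_hyp")]]$suction_delay_frac,
      stringsAsFactors = FALSE
    )
  }
  truth <- rbind(truth_row("pre"), truth_row("post"))
  truth$MRR <- (truth$CFVR / truth$FFR) *
    (sapply(c("pre", "post"), function(ph) tmpl[[paste0(ph, "_rest")]]$mean_pa) /
     sapply(c("pre", "post"), function(ph) tmpl[[paste0(ph, "_hyp")]]$mean_pa))
  truth$RRR <- truth$bMR / truth$hMR
  list(recordings = recs, truth = truth)
}

#' Generate a synthetic pre/post-PCI cohort
#'
#' Draws per-vessel parameters from the group distributions of a
#' \code{\link{cohort_spec}} and generates the four recordings per vessel.
#' Group membership is enforced on the true (noiseless) indices by rejection
#' sampling with a bounded number of draws: concordant vessels satisfy
#' post-PCI FFR > 0.8 and hSR < 0.8, discordant vessels FFR <= 0.8 and
#' hSR < 0.8. Deterministic under \code{spec$seed}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return List with \code{vessels} (list of \code{\link{synth_vessel}}
#'   outputs) and \code{truth} (data frame of per-vessel/phase ground truth
#'   with the configured group label).
#' @export
synth_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop_corowia("corowia_parameter_error", "spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_concordant + spec$n_discordant
  group <- rep(c("concordant", "discordant"),
               c(spec$n_concordant, spec$n_discordant))
  seeds <- sample.int(.Machine$integer.max - 1L, n * 4L)

  vessels <- vector("list", n)
  truth <- NULL
  for (v in seq_len(n)) {
    g <- spec$groups[[group[v]]]
    draw2 <- function(ms, lo = 0.01, hi = Inf)
      draw_trunc(function() rlnorm_ms(1, ms[1], ms[2]), lo, hi)

    pars <- NULL
    for (vessel_try in seq_len(50L)) {

    # vessel-level haemodynamic context, shared across the four recordings
    hr <- draw_trunc(function() stats::rnorm(1, 68, 8), 45, 110)
    p_sys <- draw_trunc(function() stats::rnorm(1, 125, 10), 95, 175)
    p_dia <- draw_trunc(function() stats::rnorm(1, 72, 7), 50, min(95, p_sys - 20))
    sf <- draw_trunc(function() stats::rnorm(1, 0.35, 0.03), 0.25, 0.45)

    # post-PCI resistances under the group-membership constraint
    ok <- FALSE
    for (try in seq_len(1000L)) {
      hSR_post <- draw2(g$hSR_post, lo = 0.02, hi = 3)
      hMR_post <- draw2(g$hMR_post, lo = 0.3, hi = 8)
      ffr_post <- hMR_post / (hMR_post + hSR_post)
      ok <- hSR_post < 0.8 &&
        ((group[v] == "concordant" && ffr_post > 0.8) ||
         (group[v] == "discordant" && ffr_post <= 0.8))
      if (ok) break
    }
    if (!ok)
      stop_corowia("corowia_generation_error",
                   sprintf("group constraint for vessel %d not met in 1000 draws", v))
    bMR_post <- draw_trunc(function() rlnorm_ms(1, g$bMR_post[1], g$bMR_post[2]),
                           hMR_post + 0.5, 12)
    # pre-PCI resistances constrained to the published pre-PCI FFR range
    ok <- FALSE
    for (try in seq_len(1000L)) {
      hSR_pre <- draw2(g$hSR_pre, lo = max(hSR_post, 0.05), hi = 6)
      hMR_pre <- draw2(g$hMR_pre, lo = 0.3, hi = 8)
      ffr_pre <- hMR_pre / (hMR_pre + hSR_pre)
      ok <- ffr_pre >= 0.3 && ffr_pre <= 0.92
      if (ok) break
    }
    if (!ok)
      stop_corowia("corowia_generation_error",
                   sprintf("pre-PCI constraint for vessel %d not met in 1000 draws", v))
    bMR_pre <- draw_trunc(function() rlnorm_ms(1, g$bMR_pre[1], g$bMR_pre[2]),
                          hMR_pre + 0.5, 12)

    delay <- lapply(g$delay, function(ms) draw2(ms, lo = 0.03, hi = 0.85))
    gain <- lapply(g$gain, function(ms) draw2(ms, lo = 0.15, hi = 2.5))

    mk <- function(MR, Rs, cell, cond_mult = 1) {
      beat_params(
        heart_rate = hr, p_sys = p_sys * cond_mult, p_dia = p_dia * cond_mult,
        systole_fraction = sf,
        stenosis_resistance = Rs, microvascular_resistance = MR,
        suction_delay_frac = delay[[cell]], suction_gain = gain[[cell]],
        noise_sd_p = spec$noise_sd_p, noise_sd_u = spec$noise_sd_u,
        hr_jitter_frac = spec$hr_jitter_frac,
        seed = seeds[(v - 1L) * 4L + match(cell, names(delay))]
      )
    }
    hyp_fac <- 0.95   # mild adenosine-induced aortic pressure drop
    build_pars <- function() {
      if (is.null(spec$hyperemia_velocity_multiplier)) {
        list(
          pre_rest = mk(bMR_pre, hSR_pre, "pre_rest"),
          pre_hyp = mk(hMR_pre, hSR_pre, "pre_hyp", hyp_fac),
          post_rest = mk(bMR_post, hSR_post, "post_rest"),
          post_hyp = mk(hMR_post, hSR_post, "post_hyp", hyp_fac)
        )
      } else {
        # fixed-multiplier mode: same resistances, velocity scaled directly
        m <- spec$hyperemia_velocity_multiplier
        base_pre <- mk(bMR_pre, hSR_pre, "pre_rest")
        base_post <- mk(bMR_post, hSR_post, "post_rest")
        pars <- list(
          pre_rest = base_pre,
          pre_hyp = mk(bMR_pre, hSR_pre, "pre_hyp"),
          post_rest = base_post,
          post_hyp = mk(bMR_post, hSR_post, "post_hyp")
        )
        pars$pre_hyp$u_mean <- m * beat_template(base_pre)$mean_u
        pars$post_hyp$u_mean <- m * beat_template(base_post)$mean_u
        pars
      }
    }
    pars <- build_pars()

    # waveform feasibility: the template's distal pressure must stay
    # positive; redraw the suction configuration for the rare extreme
    # delay/gain combinations that would invert it
    min_pd <- function(pp) {
      tm <- beat_template(pp)
      min(tm$pd(seq(0, tm$period, length.out = 512)))
    }
    feasible <- function(ps) all(vapply(ps, min_pd, numeric(1)) > 2)
    ftry <- 0L
    while (!feasible(pars) && ftry < 20L) {
      ftry <- ftry + 1L
      delay <- lapply(g$delay, function(ms) draw2(ms, lo = 0.03, hi = 0.85))
      gain <- lapply(g$gain, function(ms) draw2(ms, lo = 0.15, hi = 2.5))
      pars <- build_pars()
    }
    if (feasible(pars)) break
    # this haemodynamic context admits no valid suction configuration;
    # redraw the whole vessel
    pars <- NULL
    }
    if (is.null(pars))
      stop_corowia("corowia_generation_error",
                   sprintf("no feasible waveform for vessel %d in 50 redraws", v))

    vs <- synth_vessel(pars$pre_rest, pars$pre_hyp, pars$post_rest,
                       pars$post_hyp, n_beats = spec$n_beats,
                       vessel_id = sprintf("V%03d", v))
    vessels[[v]] <- vs
    tr <- vs$truth
    tr$group <- group[v]
    truth <- rbind(truth, tr)
  }
  list(vessels = vessels, truth = truth)
}

#' Generate a continuous recording spanning the hyperemia transition
#'
#' Concatenates resting beats, a linear resistance ramp emulating the onset
#' of adenosine action, and hyperemic plateau beats into one continuous
#' dual-rate recording, for exercising automatic rest/hyperemia window
#' selection.
#'
#' @param rest_params,hyp_params \code{\link{beat_params}} for the two
#'   plateaus; they must share heart rate, pressures and sampling rates.
#' @param n_rest,n_ramp,n_hyp beat counts of the three segments.
#' @param vessel_id identifier.
#' @return A \code{\link{vessel_recording}} with condition
#'   \code{"continuous"}; attribute \code{"truth"} records the segment
#'   boundaries in seconds.
#' @export
synth_continuous <- function(rest_params, hyp_params,
                             n_rest = 40, n_ramp = 6, n_hyp = 40,
                             vessel_id = "V1") {
  validate_beat_params(rest_params)
  validate_beat_params(hyp_params)
  set.seed(rest_params$seed)
  n_beats <- n_rest + n_ramp + n_hyp
  frac <- c(rep(0, n_rest), seq_len(n_ramp) / (n_ramp + 1), rep(1, n_hyp))

  mk_tmpl <- function(a) {
    p <- rest_params
    p$microvascular_resistance <-
      (1 - a) * rest_params$microvascular_resistance +
      a * hyp_params$microvascular_resistance
    p$suction_delay_frac <-
      (1 - a) * rest_params$suction_delay_frac + a * hyp_params$suction_delay_frac
    p$suction_gain <-
      (1 - a) * rest_params$suction_gain + a * hyp_params$suction_gain
    if (!is.null(rest_params$u_mean) && !is.null(hyp_params$u_mean))
      p$u_mean <- (1 - a) * rest_params$u_mean + a * hyp_params$u_mean
    beat_template(p)
  }
  tmpls <- lapply(frac, mk_tmpl)
  T0 <- tmpls[[1]]$period
  mult <- if (rest_params$hr_jitter_frac > 0)
    pmin(pmax(stats::rnorm(n_beats, 1, rest_params$hr_jitter_frac), 0.85), 1.15)
  else rep(1, n_beats)
  periods <- T0 * mult
  total <- sum(periods)
  natural <- rep(T0, n_beats)

  pa <- sample_train(lapply(tmpls, `[[`, "pa"), natural, periods,
                     rest_params$fs_pressure, total)
  pd <- sample_train(lapply(tmpls, `[[`, "pd"), natural, periods,
                     rest_params$fs_pressure, total)
  u <- sample_train(lapply(tmpls, `[[`, "u"), natural, periods,
                    rest_params$fs_velocity, total)
  if (rest_params$noise_sd_p > 0) {
    pa <- pa + stats::rnorm(length(pa), 0, rest_params$noise_sd_p)
    pd <- pd + stats::rnorm(length(pd), 0, rest_params$noise_sd_p)
  }
  if (rest_params$noise_sd_u > 0)
    u <- u + stats::rnorm(length(u), 0, rest_params$noise_sd_u)

  rec <- vessel_recording(pa, pd, u, rest_params$fs_pressure,
                          rest_params$fs_velocity, vessel_id = vessel_id,
                          phase = rest_params$phase %||% "pre",
                          condition = "continuous")
  on <- c(0, cumsum(periods))
  attr(rec, "truth") <- list(
    rest_end = on[n_rest + 1L],
    hyp_start = on[n_rest + n_ramp + 1L],
    onsets = on[seq_len(n_beats)], periods = periods
  )
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
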