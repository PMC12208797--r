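test_that("parameter validation names the violated bound", {
  expect_error(beat_params(p_sys = 60, p_dia = 70), "p_sys must exceed p_dia",
               class = "corowia_parameter_error")
  expect_error(beat_params(heart_rate = 30), "heart_rate",
               class = "corowia_parameter_error")
  expect_error(beat_params(suction_delay_frac = 1), "suction_delay_frac",
               class = "corowia_parameter_error")
  expect_error(beat_params(stenosis_resistance = -1), "stenosis_resistance",
               class = "corowia_parameter_error")
  expect_error(beat_params(fs_pressure = 150), "fs_pressure",
               class = "corowia_parameter_error")
  expect_error(synth_beat(ref_params(), 0), "n_beats",
               class = "corowia_parameter_error")
})

test_that("zero stenosis resistance gives identical Pa and Pd samplewise", {
  rec <- synth_beat(ref_params(stenosis_resistance = 0), 2)
  expect_identical(rec$pa, rec$pd)
})

test_that("noiseless 60 bpm train is exactly periodic with 1.0 s beats", {
  rec <- synth_beat(ref_params(heart_rate = 60), 3)
  n <- rec$fs_pressure          # samples per 1.0 s beat
  b <- matrix(rec$pa, nrow = n)
  expect_equal(b[, 1], b[, 2], tolerance = 1e-12)
  expect_equal(b[, 2], b[, 3], tolerance = 1e-12)
  bu <- matrix(rec$u, nrow = rec$fs_velocity)
  expect_equal(bu[, 1], bu[, 3], tolerance = 1e-12)
  # autocorrelation of the pressure peaks at the 1.0 s lag
  rec10 <- synth_beat(ref_params(heart_rate = 60), 10)
  ac <- stats::acf(rec10$pa, lag.max = round(1.4 * n), plot = FALSE)$acf[-1]
  peak_lag <- which.max(ac[(n %/% 2):length(ac)]) + n %/% 2 - 1
  expect_lte(abs(peak_lag - n), 1)
})

test_that("generation is reproducible under the seed", {
  p <- ref_params(noise_sd_p = 1, noise_sd_u = 1, hr_jitter_frac = 0.02,
                  seed = 99L)
  r1 <- synth_beat(p, 5)
  r2 <- synth_beat(p, 5)
  expect_identical(r1$pa, r2$pa)
  expect_identical(r1$u, r2$u)
  r3 <- synth_beat(ref_params(noise_sd_p = 1, seed = 100L), 5)
  expect_false(identical(r1$pa, r3$pa))
})

test_that("noiseless output satisfies Pd <= Pa wherever U >= 0", {
  for (rs in c(0, 0.3, 1.5)) for (f in c(0.1, 0.4)) {
    rec <- synth_beat(ref_params(stenosis_resistance = rs,
                                 suction_delay_frac = f), 2)
    expect_true(all(rec$pd <= rec$pa + 1e-12))
    expect_true(all(rec$u >= 0))
  }
})

test_that("ground-truth FFR equals hMR/(hMR + hSR) to 1e-12", {
  for (rs in c(0.1, 0.5, 1.2)) for (mr in c(1.5, 3)) {
    vs <- synth_vessel(
      ref_params(stenosis_resistance = rs, microvascular_resistance = mr * 2.5),
      ref_params(stenosis_resistance = rs, microvascular_resistance = mr),
      ref_params(stenosis_resistance = rs / 4, microvascular_resistance = mr * 2.5),
      ref_params(stenosis_resistance = rs / 4, microvascular_resistance = mr),
      n_beats = 1)
    with(vs$truth, expect_equal(FFR, hMR / (hMR + hSR), tolerance = 1e-12))
  }
})

test_that("synth_vessel ground truth honours construction", {
  # zero post-PCI stenosis resistance -> FFR_post exactly 1
  vs <- synth_vessel(
    ref_params(), ref_params(microvascular_resistance = 0.8),
    ref_params(stenosis_resistance = 0),
    ref_params(stenosis_resistance = 0, microvascular_resistance = 0.8),
    n_beats = 1)
  expect_equal(vs$truth$FFR[vs$truth$phase == "post"], 1, tolerance = 1e-12)

  # pinned velocity means: CFVR = 2 exactly by construction
  vs2 <- synth_vessel(
    ref_params(u_mean = 20), ref_params(u_mean = 40),
    ref_params(u_mean = 22), ref_params(u_mean = 44),
    n_beats = 1)
  expect_equal(vs2$truth$CFVR, c(2, 2), tolerance = 1e-12)

  # hyperemic velocity must exceed resting velocity
  expect_error(
    synth_vessel(ref_params(), ref_params(microvascular_resistance = 3),
                 ref_params(), ref_params(microvascular_resistance = 3),
                 n_beats = 1),
    "multiplier", class = "corowia_parameter_error")
})

test_that("ground-truth hSR is strictly increasing in stenosis resistance", {
  rs_grid <- seq(0.1, 2.5, length.out = 10)
  hsr <- vapply(rs_grid, function(rs) {
    vs <- synth_vessel(ref_params(stenosis_resistance = rs),
                       ref_params(stenosis_resistance = rs,
                                  microvascular_resistance = 0.9),
                       ref_params(stenosis_resistance = rs / 2),
                       ref_params(stenosis_resistance = rs / 2,
                                  microvascular_resistance = 0.9),
                       n_beats = 1)
    vs$truth$hSR[vs$truth$phase == "pre"]
  }, numeric(1))
  expect_true(all(diff(hsr) > 0))
  expect_equal(hsr, rs_grid, tolerance = 1e-9)
})

test_that("synth_cohort produces the requested structure deterministically", {
  spec <- cohort_spec(n_concordant = 5, n_discordant = 2, n_beats = 2,
                      noise_sd_p = 0.5, noise_sd_u = 0.5, seed = 7L)
  gen <- synth_cohort(spec)
  expect_length(gen$vessels, 7)
  expect_equal(nrow(gen$truth), 14)   # 7 vessels x 2 phases
  expect_equal(sum(gen$truth$group == "concordant"), 10)

  post <- gen$truth[gen$truth$phase == "post", ]
  conc <- post$group == "concordant"
  expect_true(all(post$FFR[conc] > 0.8 & post$hSR[conc] < 0.8))
  expect_true(all(post$FFR[!conc] <= 0.8 & post$hSR[!conc] < 0.8))

  gen2 <- synth_cohort(spec)
  expect_identical(gen$vessels[[3]]$recordings$post_hyp$pa,
                   gen2$vessels[[3]]$recordings$post_hyp$pa)
  expect_identical(gen$truth, gen2$truth)
})

test_that("cohort_spec rejects invalid group sizes and multipliers", {
  expect_error(cohort_spec(n_concordant = 1, n_discordant = 0),
               class = "corowia_parameter_error")
  expect_error(cohort_spec(hyperemia_velocity_multiplier = 1),
               class = "corowia_parameter_error")
})

test_that("fixed-multiplier hyperemia yields that CFVR exactly", {
  spec <- cohort_spec(n_concordant = 2, n_discordant = 0, n_beats = 1,
                      noise_sd_p = 0, noise_sd_u = 0, hr_jitter_frac = 0,
                      hyperemia_velocity_multiplier = 2, seed = 3L)
  gen <- synth_cohort(spec)
  expect_equal(gen$truth$CFVR, rep(2, 4), tolerance = 1e-9)
})
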