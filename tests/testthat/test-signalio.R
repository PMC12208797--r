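test_that("trace files round-trip through write/read in both dialects", {
  rec <- synth_beat(ref_params(noise_sd_p = 0.5, noise_sd_u = 0.5, seed = 4L), 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f, dialect = "block")
  back <- read_recording(f)
  expect_equal(back$pa, rec$pa, tolerance = 1e-12)
  expect_equal(back$pd, rec$pd, tolerance = 1e-12)
  expect_equal(back$u, rec$u, tolerance = 1e-12)
  expect_identical(back$vessel_id, rec$vessel_id)
  expect_equal(back$fs_velocity, rec$fs_velocity)

  rec2 <- resample_to_common_grid(rec)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec2, f2, dialect = "wide")
  back2 <- read_recording(f2)
  expect_equal(back2$u, rec2$u, tolerance = 1e-12)
  expect_equal(back2$fs_pressure, rec2$fs_pressure)
})

test_that("malformed trace files raise named format errors", {
  rec <- synth_beat(ref_params(seed = 4L), 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  lines <- readLines(f)
  pd_start <- grep("channel=Pd", lines)
  u_start <- grep("channel=U", lines)
  writeLines(lines[-(pd_start:(u_start - 1))], f)
  expect_error(read_recording(f), "Pd", class = "corowia_format_error")

  # non-monotone time column
  writeLines(c("# vessel_id=V1 phase=pre condition=rest fs=200",
               "time,Pa,Pd,U", "0,100,90,20", "0.01,100,90,20",
               "0.005,100,90,20"), f)
  expect_error(read_recording(f), "non-monotone", class = "corowia_format_error")
})

test_that("dual-rate generator output keeps a 2:1 sample-count ratio", {
  rec <- synth_beat(ref_params(fs_pressure = 200, fs_velocity = 100), 4)
  expect_equal(length(rec$pa) / length(rec$u), 2)
})

test_that("Savitzky-Golay smoothing is exact on quadratics and linear", {
  t <- seq(0, 2, by = 0.01)
  x <- 3 + 2 * t - 5 * t^2
  expect_equal(smooth_velocity(x), x, tolerance = 1e-10)
  expect_equal(smooth_velocity(rep(7, 50)), rep(7, 50), tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(smooth_velocity(2 * a + 3 * b),
               2 * smooth_velocity(a) + 3 * smooth_velocity(b),
               tolerance = 1e-10)
  expect_error(smooth_velocity(rnorm(10)), "11",
               class = "corowia_insufficient_data")
})

test_that("smoothing stencil matches an independent per-window LS fit", {
  # brute-force oracle: fit y ~ poly(x, 2) on each 11-sample window with lm()
  set.seed(2)
  y <- rnorm(41)
  sm <- smooth_velocity(y)
  xs <- -5:5
  for (c0 in c(6, 21, 36)) {
    fit <- lm(y[(c0 - 5):(c0 + 5)] ~ xs + I(xs^2))
    expect_equal(sm[c0], unname(fitted(fit)[6]), tolerance = 1e-10)
  }
})

test_that("velocity resampling preserves shape and duration", {
  p <- ref_params()
  rec <- synth_beat(p, 4)
  # identity on an already-common grid
  rec_c <- resample_to_common_grid(rec)
  again <- resample_to_common_grid(rec_c)
  expect_identical(again$u, rec_c$u)

  # sinusoid at 100 Hz resampled to 200 Hz stays within 1e-3 of closed form
  tu <- seq(0, 4 - 1 / 100, by = 1 / 100)
  u <- 20 + 10 * sin(2 * pi * tu)
  pa <- rep(100, 800); pd <- rep(90, 800)
  rec_s <- vessel_recording(pa, pd, u, 200, 100)
  out <- resample_to_common_grid(rec_s)
  tp <- (seq_along(out$u) - 1) / 200
  expect_lt(max(abs(out$u - (20 + 10 * sin(2 * pi * pmin(tp, max(tu)))))), 1e-3)

  # linear ramp is reproduced exactly
  rec_l <- vessel_recording(pa, pd, 5 + 2 * tu, 200, 100)
  out_l <- resample_to_common_grid(rec_l)
  expect_equal(out_l$u, 5 + 2 * pmin(tp, max(tu)), tolerance = 1e-9)
})

test_that("beat detection finds the pressure foot at the configured rate", {
  rec <- synth_beat(ref_params(heart_rate = 60), 12)
  bi <- detect_beats(rec$pa, rec$fs_pressure)
  iv <- diff(bi$onsets) / rec$fs_pressure
  expect_true(all(abs(iv - 1) <= 0.01))
  expect_true(all(bi$flags == "ok"))

  expect_error(detect_beats(rep(100, 2000), 200),
               class = "corowia_segmentation_error")
})

test_that("an outlier-length beat is flagged rejected", {
  # 6 beats at 60 bpm, one at 42 bpm (~43% longer), 6 more at 60 bpm
  p60 <- ref_params(heart_rate = 60)
  p42 <- ref_params(heart_rate = 42)
  a <- synth_beat(p60, 6); b <- synth_beat(p42, 1); c <- synth_beat(p60, 6)
  pa <- c(a$pa, b$pa, c$pa)
  bi <- detect_beats(pa, 200)
  iv <- diff(bi$onsets) / 200
  long <- which.max(iv)
  expect_gt(iv[long], 1.3)
  expect_identical(bi$flags[long], "rejected")
  expect_true(sum(bi$flags == "rejected") <= 2)
})

test_that("ensemble averaging is idempotent on identical beats", {
  # common grid: averaging identical beats must reproduce one beat exactly
  rec <- synth_beat(ref_params(heart_rate = 60, fs_velocity = 200), 10)
  eb <- ensemble_average(rec, truth_onsets(rec))
  expect_equal(eb$n_beats_averaged, 10)
  expect_equal(eb$pa, rec$pa[1:200], tolerance = 1e-9)
  expect_equal(eb$u, rec$u[1:200], tolerance = 1e-9)
  # dual-rate chain: interpolation touches only the recording tail, so the
  # ensemble still matches an interior beat closely
  rec2 <- synth_beat(ref_params(heart_rate = 60), 10)
  eb2 <- ensemble_average(rec2, truth_onsets(rec2))
  one <- resample_to_common_grid(rec2)
  expect_equal(eb2$pa, one$pa[201:400], tolerance = 1e-9)
  expect_equal(eb2$u, one$u[201:400], tolerance = 1e-3)
})

test_that("ensemble averaging commutes with channel scaling", {
  rec <- synth_beat(ref_params(noise_sd_p = 1, noise_sd_u = 1, seed = 8L), 10)
  bi <- truth_onsets(rec)
  eb <- ensemble_average(rec, bi)
  rec2 <- rec
  rec2$pa <- 3 * rec2$pa; rec2$pd <- 3 * rec2$pd; rec2$u <- 3 * rec2$u
  eb2 <- ensemble_average(rec2, bi)
  expect_equal(eb2$pa, 3 * eb$pa, tolerance = 1e-12)
  expect_equal(eb2$u, 3 * eb$u, tolerance = 1e-12)
})

test_that("fewer than 8 accepted beats raises a counting error", {
  rec <- synth_beat(ref_params(heart_rate = 60), 7)
  err <- expect_error(ensemble_average(rec, truth_onsets(rec)),
                      class = "corowia_insufficient_beats")
  expect_match(conditionMessage(err), "7")
  expect_equal(err$n_beats, 7)
})

test_that("window selection locates the hyperemic plateau", {
  rest <- ref_params(heart_rate = 75, microvascular_resistance = 5,
                     suction_delay_frac = 0.2, noise_sd_p = 0.3,
                     noise_sd_u = 0.3, seed = 21L)
  hyp <- ref_params(heart_rate = 75, microvascular_resistance = 2,
                    suction_delay_frac = 0.2)
  cont <- synth_continuous(rest, hyp, n_rest = 40, n_ramp = 6, n_hyp = 40)
  ws <- select_windows(cont)
  tr <- attr(cont, "truth")
  beat_len <- 60 / 75
  # hyperemia window must open within ~2 beats of the true plateau onset
  expect_gt(ws$hyperemia_window[1], tr$rest_end)
  expect_lt(abs(ws$hyperemia_window[1] - tr$hyp_start), 2 * beat_len)
  expect_lt(ws$rest_window[2], ws$hyperemia_window[1])
  # both windows feed >= 8 beats to the ensemble
  rec_c <- resample_to_common_grid(cont)
  eb_r <- ensemble_average(rec_c, ws$beats, ws$rest_window)
  eb_h <- ensemble_average(rec_c, ws$beats, ws$hyperemia_window)
  expect_gte(eb_r$n_beats_averaged, 8)
  expect_gte(eb_h$n_beats_averaged, 8)
  expect_gt(time_average(eb_h, "u"), 1.5 * time_average(eb_r, "u"))
})

test_that("window selection fails on a flat recording and prefers the later of tied plateaus", {
  rest <- ref_params(heart_rate = 75, microvascular_resistance = 5, seed = 22L)
  flat <- synth_beat(rest, 60)
  expect_error(select_windows(flat), class = "corowia_selection_error")

  hyp <- ref_params(heart_rate = 75, microvascular_resistance = 2)
  seg1 <- synth_beat(rest, 25); seg2 <- synth_beat(hyp, 25)
  seg3 <- synth_beat(rest, 15); seg4 <- synth_beat(hyp, 25)
  two <- vessel_recording(
    c(seg1$pa, seg2$pa, seg3$pa, seg4$pa),
    c(seg1$pd, seg2$pd, seg3$pd, seg4$pd),
    c(seg1$u, seg2$u, seg3$u, seg4$u),
    200, 100, condition = "continuous")
  ws <- select_windows(two)
  t_second_plateau <- (25 + 25 + 15) * (60 / 75)
  expect_gt(ws$hyperemia_window[1], t_second_plateau - 3 * (60 / 75))
  expect_gt(ws$hyperemia_window[2], t_second_plateau)
})
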