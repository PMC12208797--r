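sin_beat <- function(fs = 200, pd_amp = 10, u_amp = 10, u_phase = 0,
                     pd_mean = 100, u_mean = 30) {
  # one 1-second cycle; u in cm/s (u_amp = 10 cm/s = 0.1 m/s)
  t <- (0:(fs - 1)) / fs
  ensemble_beat(t,
                pa = pd_mean + pd_amp * sin(2 * pi * t),
                pd = pd_mean + pd_amp * sin(2 * pi * t),
                u = u_mean + u_amp * sin(2 * pi * t + u_phase),
                fs = fs, n_beats_averaged = 8L)
}

test_that("differentiation is exact on ramps and accurate on sinusoids", {
  fs <- 200
  t <- (0:(2 * fs - 1)) / fs
  b <- ensemble_beat(t, pa = 50 + 5 * t, pd = 50 + 5 * t,
                     u = 100 * sin(2 * pi * t), fs = fs)
  d <- differentiate(b)
  interior <- 20:(length(t) - 20)
  expect_equal(d$dPdt[interior], rep(5 * 133.322, length(interior)),
               tolerance = 1e-3)
  # dU/dt of sin(2*pi*t) m/s peaks at 2*pi m/s^2
  expect_equal(max(d$dUdt[interior]), 2 * pi, tolerance = 5e-3)
  # constant channels give zero derivatives
  b0 <- ensemble_beat(t, rep(100, length(t)), rep(90, length(t)),
                      rep(20, length(t)), fs = fs)
  d0 <- differentiate(b0)
  expect_lt(max(abs(d0$dPdt)), 1e-10)
  expect_lt(max(abs(d0$dUdt)), 1e-10)
})

test_that("net wave intensity matches the closed form for in-phase sinusoids", {
  b <- sin_beat()
  prof <- net_wave_intensity(b)
  peak_expected <- 10 * 133.322 * 0.1 * (2 * pi)^2
  expect_true(all(prof$wi >= -1e-9))
  expect_equal(max(prof$wi), peak_expected, tolerance = 0.01)
  # quadrant partition reconstructs WI pointwise exactly
  recon <- rep(0, length(prof$wi))
  for (q in c("FCW", "BCW", "FEW", "BEW"))
    recon <- recon + ifelse(!is.na(prof$quadrant) & prof$quadrant == q,
                            prof$wi, 0)
  recon <- recon + ifelse(is.na(prof$quadrant), prof$wi, 0)
  expect_identical(recon, prof$wi)
  # only in-phase quadrants appear
  expect_true(all(prof$quadrant[!is.na(prof$quadrant)] %in% c("FCW", "FEW")))
})

test_that("antiphase velocity flips the sign and the quadrant occupancy", {
  b <- sin_beat(u_phase = pi)
  prof <- net_wave_intensity(b)
  expect_true(all(prof$wi <= 1e-9))
  expect_true(all(prof$quadrant[!is.na(prof$quadrant)] %in% c("BCW", "BEW")))
  pk <- extract_peaks(prof)
  expect_true(is.na(pk$FCW_peak))   # forward compression absent
  expect_false(is.na(pk$BEW_peak))  # suction wave present
})

test_that("flat beats are rejected as degenerate", {
  t <- (0:199) / 200
  b <- ensemble_beat(t, rep(100, 200), rep(90, 200), rep(20, 200), fs = 200)
  expect_error(net_wave_intensity(b), class = "corowia_degenerate_beat")
})

test_that("suction-wave timing is recovered from generator beats", {
  p <- ref_params(suction_delay_frac = 0.25)
  eb <- analyze_recording(synth_beat(p, 16))
  pk <- extract_peaks(net_wave_intensity(eb))
  expect_lt(abs(pk$tBEW_peak - 0.25), 0.03)
  expect_gte(pk$tBEW_peak, 0)
  expect_lte(pk$tBEW_peak, 1)
})

test_that("wave intensity is bilinear in the channels; tBEW is scale-free", {
  p <- ref_params(suction_delay_frac = 0.3)
  eb <- analyze_recording(synth_beat(p, 16))
  pk <- extract_peaks(net_wave_intensity(eb))
  eb2 <- eb
  eb2$pd <- 2 * eb2$pd; eb2$pa <- 2 * eb2$pa
  eb2$u <- 3 * eb2$u
  pk2 <- extract_peaks(net_wave_intensity(eb2))
  for (w in c("FCW_peak", "BCW_peak", "FEW_peak", "BEW_peak"))
    expect_equal(pk2[[w]], 6 * pk[[w]], tolerance = 1e-9)
  expect_equal(pk2$tBEW_peak, pk$tBEW_peak, tolerance = 1e-12)
  expect_equal(pk2$accel_energy_fraction, pk$accel_energy_fraction,
               tolerance = 1e-9)
})

test_that("weaker suction lowers the BEW peak at matched mean velocity", {
  base <- ref_params(suction_delay_frac = 0.25, suction_gain = 1,
                     u_mean = 48)
  weak <- ref_params(suction_delay_frac = 0.25, suction_gain = 0.5,
                     u_mean = 48)
  eb1 <- analyze_recording(synth_beat(base, 16))
  eb2 <- analyze_recording(synth_beat(weak, 16))
  pk1 <- extract_peaks(net_wave_intensity(eb1))
  pk2 <- extract_peaks(net_wave_intensity(eb2))
  expect_lt(pk2$BEW_peak, pk1$BEW_peak)
  expect_equal(time_average(eb2, "u"), time_average(eb1, "u"),
               tolerance = 0.05)
})

test_that("accelerating energy fraction behaves per definition", {
  # symmetric in-phase case: half the energy in FCW, half in FEW
  prof <- net_wave_intensity(sin_beat())
  expect_equal(accel_energy_fraction(prof), 0.5, tolerance = 0.01)

  # hand-built profile with only accelerating labels gives exactly 1
  n <- 100
  t <- (0:(n - 1)) / n
  wi <- sin(2 * pi * t)
  q <- ifelse(wi >= 0, "FCW", "BEW")
  prof1 <- structure(list(time = t, dPdt = wi, dUdt = rep(1, n), wi = wi,
                          quadrant = q, expansion_start = 0.5,
                          expansion_end = 1, fs = n),
                     class = "wia_profile")
  expect_equal(accel_energy_fraction(prof1), 1, tolerance = 1e-12)

  # BEW peak exactly at the expansion onset gives tBEW_peak = 0
  q2 <- rep(NA_character_, n)
  q2[t >= 0.2 & t < 0.5] <- "FCW"
  q2[t >= 0.5] <- "BEW"
  wi2 <- ifelse(t >= 0.5, -exp(-(t - 0.5) * 5), 1)
  prof2 <- structure(list(time = t, dPdt = wi2, dUdt = rep(1, n), wi = wi2,
                          quadrant = q2, expansion_start = 0.5,
                          expansion_end = 1, fs = n),
                     class = "wia_profile")
  pk <- extract_peaks(prof2)
  expect_equal(pk$tBEW_peak, 0, tolerance = 1e-12)

  # missing suction wave raises a classed error
  q3 <- ifelse(t < 0.5, "FCW", "FEW")
  prof3 <- structure(list(time = t, dPdt = wi, dUdt = rep(1, n), wi = wi,
                          quadrant = q3, expansion_start = 0.5,
                          expansion_end = 1, fs = n),
                     class = "wia_profile")
  expect_error(extract_peaks(prof3), class = "corowia_missing_wave")
})
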