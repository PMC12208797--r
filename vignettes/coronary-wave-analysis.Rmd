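---
title: "Methods: coronary wave intensity and hemodynamic index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coronary wave intensity and hemodynamic index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corowia)
```

## Scope and model

`corowia` analyses simultaneous intracoronary recordings of aortic pressure
(Pa), distal coronary pressure (Pd) and Doppler average peak velocity (U).
The pipeline has four stages:

1. **Signal conditioning and beat extraction.** The velocity envelope is
   smoothed with a second-order Savitzky–Golay filter (11-sample window) on
   its native grid, then upsampled to the pressure grid; beats are
   delimited at the diastolic pressure foot; accepted beats are
   time-normalised and ensemble-averaged into one representative cycle
   (at least 8 beats).
2. **Conventional indices** from time-averages over that cycle:
   FFR = ⟨Pd⟩/⟨Pa⟩ (hyperemia), CFVR = ⟨U_hyp⟩/⟨U_rest⟩,
   hSR = (⟨Pa⟩−⟨Pd⟩)/⟨U⟩ (hyperemia), bMR and hMR = ⟨Pd⟩/⟨U⟩ per state,
   MRR = (CFVR/FFR)·(⟨Pa_rest⟩/⟨Pa_hyp⟩), RRR = bMR/hMR. Two identities
   follow algebraically from these definitions and serve as permanent
   self-checks: FFR = hMR/(hMR+hSR) and MRR = RRR·(⟨Pa_rest⟩/⟨Pd_rest⟩).
3. **Net wave-intensity analysis**: WI(t) = (dP/dt)(dU/dt) in W·m⁻²·s⁻²
   on the ensemble beat, quadrant classification of the four canonical
   waves by derivative signs, peak extraction, the relative suction-wave
   timing tBEW_peak, and the accelerating-energy fraction
   (FCW + BEW energy over all labeled energy).
4. **Cohort statistics** with the conventional normality-gated test
   selection, producing paired pre/post tables, concordant-vs-discordant
   contrasts, wave-peak tables and pressure-drop correlations.

Assumptions: one dominant systolic pressure peak per cycle; diastole-
dominant coronary flow; beats comparable after linear time rescaling;
sensor noise approximately additive and white at the sample level.

## Key parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| SG filter order / window | – / samples | 2 / 11 | standard envelope smoothing; exact on locally quadratic signals |
| minimum beats per ensemble | beats | 8 | conventional floor for stable coronary WIA |
| beat rejection band | – | ±20% of running-median cycle length | surrogate for a manual signal-quality screen |
| admissible cycle length | s | 0.33–1.5 | 40–180 bpm physiological band |
| quadrant dead-band | – | 1% of each derivative's own max | suppresses spurious labels near zero crossings; peaks are max-based so amplitudes are unaffected |
| classification cut-offs | – | FFR abnormal ≤ 0.80; hSR normal < 0.80 | printed boundary conventions, ties resolved exactly as written |
| mmHg → Pa | – | 133.322 | SI conversion for WI |
| reported WI peak unit | – | 10 kW·m⁻²·s⁻² = 10⁴ W·m⁻²·s⁻² | conventional reporting unit |
| normality gate | – | Shapiro–Wilk p < 0.05, per group | matches the global significance convention |

## Decisions where the method was genuinely open

- **Net-WI quadrants rather than wave-speed separation.** Forward/backward
  separation requires a single-point wave-speed estimate that dual-sensor
  coronary recordings support only with additional assumptions. The net
  profile preserves the four-wave structure used here; `extract_peaks()`
  is isolated behind the profile object so a separated-WI backend could be
  added without touching callers.
- **Expansion phase anchored at the distal (Pd) systolic maximum,** ending
  at the cycle end. WIA operates on the distal sensor pair, so the distal
  peak is the natural anchor; with the generator's waveforms the Pa and Pd
  peaks coincide to within a sample when the translesional drop is flat
  around the peak.
- **Beat landmark: pressure-foot onset** via a dP/dt-threshold-then-minimum
  search with a 0.33 s refractory period — the standard pulse-waveform foot
  algorithm; robust on aortic traces.
- **Time normalisation before averaging** by linear rescaling to the median
  cycle length, preventing diastolic smearing when heart rate varies; this
  also makes the analyzer exactly invert the generator's cycle-length
  jitter (which dilates the template linearly).
- **Window selection score.** The hyperemic window is the contiguous
  plateau of the 10-beat rolling mean of beat-mean velocity (relative slope
  below 2% per beat) with the highest mean, ties broken toward later onset;
  because a trailing rolling mean flags a plateau late, the window start is
  then walked backward over beats already within 3% of the plateau level.
  The resting window is the minimum-variance 15 s span before the rise.
  Both operationalise "maximum mean change with visual confirmation" as an
  automatic criterion and log their scores in `method_trace`.
- **Averages over the ensemble beat, not the raw window,** so conventional
  indices and WIA share one representative cycle; the difference is
  second-order for mean-based indices.
- **Student's (equal-variance) t-test on the normal path** as printed for
  this literature; Welch is available behind a flag. No multiple-testing
  correction is applied (the report notes this), mirroring exploratory
  practice.

## Numerical choices

- SG filtering uses the least-squares stencil; boundaries are handled by
  evaluating the end-window fits off-centre (open recordings) or cyclically
  (the periodic ensemble beat, used for WIA derivatives). Derivatives are
  exact on quadratics; on a 1 Hz sinusoid sampled at 200 Hz the amplitude
  error is below 0.5%.
- Velocity upsampling uses shape-preserving monotone Hermite interpolation
  (no overshoot on envelope-like data); pressure is never downsampled, so
  the dP/dt bandwidth is preserved.
- Time-averages use the trapezoidal rule over the spanned cycle. Wave
  *energies* integrate |WI| with rectangle weights on the wrapped periodic
  cycle, so a quadrant's energy does not depend on where the array boundary
  happens to cut its mask.
- Degenerate inputs raise classed conditions rather than silent NAs:
  non-positive mean flow or pressure, flat channels, empty table margins,
  a missing suction wave (`corowia_missing_wave`; the vessel is flagged and
  excluded from wave tables, never zero-filled), fewer than 8 accepted
  beats (`corowia_insufficient_beats`, reporting the count), and paired
  samples with zero-variance differences (p reported as exactly 1 or 0
  with a `degenerate_variance` flag).

## The synthetic generator: stated world

The generator is first-class, tested code: it produces the data the
analysis assumes, with exact ground truth.

**Waveform template.** Aortic pressure is a raised-cosine systolic upstroke
peaking at `systole_fraction` of the cycle, followed by an exponential
diastolic decay (time constant one third of the expansion span). Velocity
is a baseline plus a small systolic lobe (ending before the pressure peak,
creating the decelerating/compressing interval that carries the BCW) and a
dominant diastolic lobe whose raised-cosine rise is centred so that the
*acceleration* peak — the substrate of the suction wave — falls at
`suction_delay_frac` of the expansion phase. Distal pressure is
Pd(t) = Pa(t) − Rs·U(t) pointwise before noise, so ⟨U⟩ = ⟨Pa⟩/(MR + Rs)
and the noiseless ground truth satisfies FFR = hMR/(hMR + hSR) exactly
(hSR = Rs, hMR = MR by construction). A simple piecewise template was
chosen over a Windkessel ODE as the simplest form producing all four
canonical quadrant waves.

**Phasicity damping.** The velocity lobes are scaled by (MR/(MR+Rs))³: a
severe stenosis flattens the distal velocity envelope, and the cubic law
guarantees the translesional drop Rs·U(t) never inverts the distal
pressure across the admissible parameter space. A residual feasibility
check in the cohort sampler (template minimum Pd > 2 mmHg) rejects the
rare extreme delay/gain combinations.

**Cohort stated world.** Group sizes default to 53 concordant / 10
discordant vessels. Post-PCI resistances are drawn log-normally around the
published group characteristics of such cohorts (concordant hSR 0.21,
hMR 1.84; discordant hSR 0.52, hMR 1.48 mmHg·cm⁻¹·s) — values that are
internally consistent with FFR = hMR/(hMR+hSR) and with matched hyperemic
velocity near 48 cm/s. Pre-PCI draws are constrained to FFR ∈ [0.3, 0.92].
Suction timing defaults to the published per-cell means (discordant
hyperemic post-PCI delay +0.09 of the expansion phase) and the discordant
post-PCI suction gain is 35% weaker. Log-normal shapes were chosen once for
all positive skewed quantities (spread comparable to the mean implies
right skew). Between-vessel spreads for the suction parameters are set by a
prospective power analysis — the largest spread, never exceeding the
published SD, that retains ~80% power for the configured group difference
at 53/10 — because published SDs include measurement noise that the
generator injects separately (sensor noise, beat-to-beat jitter).
Rejection sampling (capped at 1000 draws per constraint) enforces group
membership on the *true* indices; note that conditioning a discordant
vessel on FFR ≤ 0.8 truncates its hMR distribution from above, so realized
group gaps in hMR are slightly wider than the configured means — an
intrinsic property of defining groups by thresholds.

**What the generator does not emulate**, hence what a green test does not
establish: no arrhythmia or ectopy, no catheter damping, drift or whip
artifacts beyond additive Gaussian noise, no pressure-wire signal loss, no
genuinely phasic (non-resistive) stenosis behaviour — in the generator the
discordant group's low FFR arises from its resistance configuration, so
end-to-end tests validate *recovery* of delayed/weaker suction and the
dissociation pattern, not the physiological coupling mechanism itself.

## Limitations

- Net WI conflates forward and backward waves where they overlap in time;
  amplitudes are not directly comparable to separated-WI software.
- The suction-wave timing contract (recovered tBEW within 0.03 of the
  configured delay) is guaranteed for delays in roughly [0.03, 0.85] of the
  expansion phase; outside that band the template clips the lobe geometry.
- Window selection assumes a single sustained hyperemic plateau (continuous
  adenosine); bolus-shaped responses with a sharp peak and quick washout
  would need a different score.
- Group comparisons at 53/10 with a true underlying difference (the
  matched-velocity constraint forces lower discordant hMR) are
  underpowered in the conventional sense: single simulated cohorts can
  reject equality of hMR even though the configured world mirrors a study
  that did not. This is a property of the stated world, not of the
  pipeline.
- Vessels are treated as independent even when two share a patient,
  reproducing conventional practice for such cohorts.
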