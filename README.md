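# corowia

Coronary wave intensity and hemodynamic index analysis in R.

## The problem

After angiographically successful stenting (PCI), a sizeable fraction of
coronary vessels retain an abnormal fractional flow reserve (FFR ≤ 0.80)
even though the stenosis itself is no longer flow-limiting (normal hyperemic
stenosis resistance, hSR < 0.8 mmHg·cm⁻¹·s). Understanding this
pressure–flow discordance requires looking past time-averaged indices at
the *phasic* interaction between the contracting/relaxing myocardium and
coronary inflow — cardiac–coronary coupling — which wave-intensity analysis
(WIA) quantifies. `corowia` is a reusable pipeline for exactly this
analysis: it takes simultaneous recordings of aortic pressure (Pa, mmHg),
distal coronary pressure (Pd, mmHg) and Doppler average peak velocity
(U, cm/s), and produces per-vessel indices, wave peaks, suction-wave timing
and cohort-level group contrasts. It is aimed at researchers working with
dual-sensor (pressure + Doppler) guidewire data or building simulation
studies of coronary physiology.

## What it computes

Time-averages ⟨·⟩ are taken over an ensemble-averaged representative beat
(≥ 8 accepted beats, time-normalised to the median cycle length).

Conventional indices, per vessel and phase (pre/post PCI):

- FFR = ⟨Pd⟩/⟨Pa⟩ during hyperemia; CFVR = ⟨U_hyp⟩/⟨U_rest⟩
- hSR = (⟨Pa⟩ − ⟨Pd⟩)/⟨U⟩ during hyperemia; ΔP = ⟨Pa⟩ − ⟨Pd⟩
- bMR = ⟨Pd_rest⟩/⟨U_rest⟩, hMR = ⟨Pd_hyp⟩/⟨U_hyp⟩
- MRR = (CFVR/FFR)·(⟨Pa_rest⟩/⟨Pa_hyp⟩), RRR = bMR/hMR

Net wave intensity on the ensemble beat,

    WI(t) = dP/dt · dU/dt   [W·m⁻²·s⁻²],

with derivatives from a Savitzky–Golay (order 2, window 11) filter after SI
conversion, classified into the four canonical coronary waves by derivative
signs: FCW and BCW (forward/backward compression), FEW and BEW
(forward/backward expansion). The backward expansion wave (BEW) is the
microvascular *suction* wave of myocardial relaxation that drives
diastole-dominant coronary filling; its relative timing

    tBEW_peak = (t_BEW − t_peak_pressure) / (expansion duration)

is heart-rate independent by construction. Peak amplitudes are reported in
10 kW·m⁻²·s⁻². Cohort statistics follow the conventional gate: Shapiro–Wilk
normality decides between Student's t and Mann–Whitney (or paired
t/Wilcoxon, chi-square/Fisher, Pearson/Spearman).

A synthetic waveform generator (`synth_beat`, `synth_vessel`,
`synth_cohort`, `synth_continuous`) produces physiologically structured
recordings with exact ground truth (the noiseless generator satisfies
FFR = hMR/(hMR + hSR) identically), including a full 63-vessel pre/post-PCI
cohort whose discordant group has delayed, weaker suction at matched
hyperemic velocity.

## Worked example

```r
library(corowia)

rest <- beat_params(heart_rate = 65, stenosis_resistance = 0.45,
                    microvascular_resistance = 4.8, suction_delay_frac = 0.22,
                    noise_sd_p = 1, noise_sd_u = 1, seed = 101)
hyp  <- beat_params(heart_rate = 65, stenosis_resistance = 0.45,
                    microvascular_resistance = 1.7, suction_delay_frac = 0.24,
                    noise_sd_p = 1, noise_sd_u = 1, seed = 102)
eb_rest <- analyze_recording(synth_beat(rest, 16, condition = "rest"))
eb_hyp  <- analyze_recording(synth_beat(hyp, 16, condition = "hyperemia"))

ind <- compute_indices(eb_rest, eb_hyp, vessel_id = "LAD-01", phase = "post")
ind
#> <hemo_indices> LAD-01 [post-PCI]
#>   FFR 0.79  CFVR 2.44  hSR 0.451 mmHg.cm-1.s  deltaP 18.5 mmHg
#>   bMR  4.8  hMR  1.7 mmHg.cm-1.s  MRR 3.09  RRR 2.82
#>   bAPV 16.8  hAPV 40.9 cm/s
classify_vessel(ind)
#> [1] "discordant"

extract_peaks(net_wave_intensity(eb_hyp))
#> <wave_peaks> amplitudes in 10 kW.m-2.s-2
#>   FCW 2.39 (t=0.125)  BCW 3.49 (t=0.235)
#>   FEW 0.43 (t=0.570)  BEW 13.7 (t=0.470)
#>   tBEW_peak 0.262 of expansion, accelerating energy fraction 0.776
```

Reading: despite a healthy hyperemic flow (hAPV ≈ 41 cm/s, CFVR ≈ 2.4) and
a normal stenosis resistance (hSR ≈ 0.45 < 0.8), this vessel's FFR of 0.79
is abnormal — the residual-low-FFR ("discordant") pattern. The recovered
suction-wave timing (0.262 of the expansion phase) matches the configured
generator truth (0.24) within the pipeline's documented tolerance.

Cohort-level analysis takes a list of per-vessel results:

```r
gen <- synth_cohort(cohort_spec(seed = 1))
results <- lapply(gen$vessels, function(v) do.call(analyze_vessel, v$recordings))
build_tables(results)   # paired pre/post, group and WIA tables, correlations
```

Recordings round-trip through a plain-text trace format
(`write_recording()`/`read_recording()`, dual-rate block or wide dialect),
and continuous recordings spanning the adenosine transition are windowed
automatically (`select_windows()`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the full synthetic study cohort under the given seed, runs
every vessel through the complete pipeline (beat detection, ensemble
averaging, indices, wave-intensity peaks), prints the cohort report and
writes the results JSON.
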