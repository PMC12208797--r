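Package: corowia
Title: Coronary Wave Intensity and Hemodynamic Index Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous intracoronary pressure and
    Doppler velocity recordings. Provides Savitzky-Golay smoothing and
    differentiation, beat detection and ensemble averaging of cardiac
    cycles, computation of conventional pressure-velocity indices
    (FFR, CFVR, hSR, bMR, hMR, MRR, RRR), net wave-intensity analysis
    with extraction of the four canonical coronary waves and the relative
    timing of the backward expansion (suction) wave, cohort-level group
    comparison with normality-gated test selection, and a physiologically
    structured synthetic waveform generator with known ground truth for
    validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
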