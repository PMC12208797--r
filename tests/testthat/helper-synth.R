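# Shared fixtures, built in code at test time.

# Noiseless reference parameters used across files.
ref_params <- function(...) {
  args <- list(...)
  defaults <- list(heart_rate = 60, p_sys = 120, p_dia = 70,
                   systole_fraction = 0.35, stenosis_resistance = 0.5,
                   microvascular_resistance = 2, suction_delay_frac = 0.25,
                   seed = 11L)
  do.call(beat_params, utils::modifyList(defaults, args))
}

# Beat boundaries (1-based sample indices) from generator truth.
truth_onsets <- function(rec) {
  tr <- attr(rec, "truth")
  bounds <- c(0, cumsum(tr$periods))
  beat_index(round(bounds * rec$fs_pressure) + 1L, rec$fs_pressure)
}

# One full synthetic study cohort analysed end to end, generated once per
# test session (shared by the stratification and group-contrast checks).
get_demo_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      gen <- synth_cohort(cohort_spec(seed = seed))
      results <- lapply(gen$vessels, function(v) do.call(analyze_vessel, v$recordings))
      cache[[key]] <- list(gen = gen, results = results)
    }
    cache[[key]]
  }
})
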