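# Shared setup for the numbered analysis scripts: every script rebuilds the
# seeded cohort (deterministic, a few seconds) so no binary intermediates
# are needed between steps.

library(longiplasma)

analysis_cohort <- function(seed = 1L) {
  cohort <- simulate_cohort(sim_config(seed = seed))
  norm <- suppressWarnings(normalize_pipeline(cohort$dataset))
  cohort$normalized <- norm$dataset
  cohort$audit <- norm$audit
  cohort
}
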