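#!/usr/bin/env Rscript

# Build the synthetic wellness cohort the whole analysis runs on:
# 101 individuals, 4 quarterly visits, 200 antibodies assayed in duplicate
# on 96-well plates, with planted plate/sample artefacts, stable and
# unstable proteins, 8 co-expression modules, 2 seasonal proteins,
# 15 cis-pQTLs and sporadic individual deviations. Ground truth is kept
# for the later recovery checks.

library(longiplasma)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 1L)
cohort <- simulate_cohort(cfg)

write_protein_dataset(cohort$dataset,
                      "results/intensities_raw.tsv",
                      "results/sample_meta.tsv")
write_report(cohort$traits, "results/traits.tsv")
write_report(cohort$truth$proteins, "results/truth_proteins.tsv")
write_report(cohort$truth$deviants, "results/truth_deviants.tsv")

cat(sprintf("cohort: %d assay samples x %d antibodies, %d individuals\n",
            nrow(cohort$dataset$intensities),
            ncol(cohort$dataset$intensities),
            length(unique(cohort$dataset$meta$individual_id))))
cat(sprintf("planted: %d modules, %d seasonal proteins, %d cis-pQTLs, %d deviant profiles\n",
            cfg$n_modules, cfg$n_seasonal, cfg$n_cis_effects,
            nrow(cohort$truth$deviants)))
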