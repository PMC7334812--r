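#!/usr/bin/env Rscript

# Per-individual deviation signatures on the stable protein set: z-score
# the cohort, fit each individual's linear profile per protein, flag
# baseline/trend/fluctuation statistics beyond +/-3 SD of the population,
# and summarize per individual and per protein; plus inter-individual
# IQR diversity.

source("analysis/00_common.R")
co <- analysis_cohort()

stab <- classify_stability(inter_assay_icc(co$normalized),
                           inter_visit_icc(co$normalized))
stable_set <- stab$table$antibody[stab$table$class == "both_stable"]
cat(sprintf("scoring %d stable proteins\n", length(stable_set)))

pz <- population_zscore(co$normalized, stable_set)
stats <- profile_statistics(pz$z, pz$info)
flags <- flag_deviations(stats)
print(flags)
summ <- summarize_signatures(flags)
write_report(flags$flags, "results/signature_flags.tsv")
write_report(summ$per_individual, "results/signature_per_individual.tsv")
write_report(summ$per_protein, "results/signature_per_protein.tsv")
jsonlite::write_json(as.list(summ$venn), "results/signature_venn.json",
                     auto_unbox = TRUE)

cat(sprintf("%d/%d profiles flagged (%.1f%%); chance %.2f%% per criterion\n",
            summ$overall$numerator, summ$overall$denominator,
            100 * summ$overall$fraction, 100 * flags$chance_rate))

dv <- subset(co$truth$deviants,
             criterion == "baseline" & antibody %in% stable_set)
key <- paste(flags$flags$individual_id, flags$flags$antibody)
got <- flags$flags$baseline[match(paste(dv$individual_id, dv$antibody), key)]
cat(sprintf("planted baseline deviants flagged: %d/%d\n",
            sum(got), length(got)))

iqr <- interindividual_iqr(pz$z, pz$info)
write_report(iqr, "results/interindividual_iqr.tsv")
cat(sprintf("IQR of individual means: median %.2f (low-diversity <= 0.15: %d, high >= 1.5: %d)\n",
            median(iqr$iqr), sum(iqr$diversity == "low"),
            sum(iqr$diversity == "high")))
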