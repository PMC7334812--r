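#!/usr/bin/env Rscript

# Technical vs longitudinal repeatability: ICC(3,1) over duplicate assays
# (inter-assay) and over visits (inter-visit), four-way stability classes
# at ICC >= 0.8, plus per-individual signature identifiability.

source("analysis/00_common.R")
co <- analysis_cohort()

stab <- classify_stability(inter_assay_icc(co$normalized),
                           inter_visit_icc(co$normalized))
print(stab)
write_report(stab$table, "results/stability.tsv")

tr <- co$truth$proteins
called <- stab$table$icc_intervisit >= 0.8
cat(sprintf("designation recovery (balanced accuracy): %.1f%%\n",
            100 * mean(c(mean(called[tr$stable_true]),
                         mean(!called[!tr$stable_true])))))

idf <- individual_identifiability(co$normalized)
print(idf)
write_report(idf$per_individual, "results/identifiability.tsv")
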