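#!/usr/bin/env Rscript

# Per-visit co-expression modules (unsigned adjacency, topological
# overlap, average-linkage clustering with a static cut) and the
# cross-visit core patterns obtained by greedy maximal-Jaccard matching
# of module memberships between consecutive visits.

source("analysis/00_common.R")
co <- analysis_cohort()

vm <- suppressWarnings(modules_per_visit(co$normalized))
for (v in vm) print(v)

core <- match_core_modules(vm)
print(core)
write_report(core$assignment, "results/core_modules.tsv")
write_report(core$patterns, "results/core_patterns.tsv")

tr <- co$truth$proteins
ari <- vapply(vm, function(v)
  mclust::adjustedRandIndex(v$labels[tr$antibody], tr$module), 0)
cat(sprintf("module recovery ARI per visit: %s (mean %.2f)\n",
            paste(round(ari, 2), collapse = ", "), mean(ari)))

mt <- module_trait_association(core, co$normalized, co$traits,
                               trait_names = grep("^trait",
                                                  names(co$traits),
                                                  value = TRUE))
write_report(mt, "results/module_trait_associations.tsv")
cat(sprintf("%d core-pattern x trait x visit tests; %d at FDR < 0.01\n",
            nrow(mt), sum(mt$significant)))
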