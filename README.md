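# longiplasma

Longitudinal plasma proteome variability analysis for multiplexed
antibody (suspension bead array) cohorts: the same individuals donate
blood at several visits, every sample is measured as median fluorescence
intensity (MFI) per antibody, and the questions are *which proteins can
be measured reliably, which are stable within a person over a year, how
proteins co-vary in networks over time, which levels are set by genetics,
and which individual profiles deviate from the cohort*.

The package is aimed at analysts of wellness-style cohorts (≈100
individuals × 4 visits × several hundred antibodies, aliquots assayed in
duplicate on 96-well plates). Because such data are typically
access-controlled, it includes a synthetic cohort generator with full
ground truth, so the entire pipeline is exercised and validated without
any download.

## What it computes

* **Normalization** — per plate: log MFI, absolute probabilistic
  quotient normalization (AbsPQN; removes per-sample scaling via the
  median difference from the plate's reference profile, iterated to its
  fixed point, grand median restored), then Multi-MA (equalizes
  per-antibody plate means, preserving the across-plate average).
* **Stability** — per antibody, intraclass correlation
  ICC(3,1) = (MS_R − MS_E)/(MS_R + (k−1)·MS_E) over duplicate assays
  (technical) and over visits (longitudinal); four-way classification at
  ICC ≥ 0.8; per-individual identifiability (ICC across visits with
  proteins as targets, nearest-neighbour self-matching).
* **Associations** — random-intercept mixed models
  (protein ~ trait + (1 | individual), lmerTest) with BH-FDR over the
  protein × trait grid (flag at FDR ≤ 0.001), and an annual
  first-harmonic seasonal scan (2-df likelihood-ratio test, flag at
  FDR < 0.01).
* **Co-expression** — per visit: unsigned adjacency |cor|^β, topological
  overlap ω, average-linkage clustering with a static cut, module
  eigengenes; across visits: core patterns from greedy maximal-Jaccard
  matching of module memberships, plus eigengene–trait tests.
* **cis-pQTLs** — MAF/HWE QC, additive per-SNP regression of across-visit
  mean levels, Bonferroni threshold α/M, cis annotation against gene
  windows, LD proxies (r² ≥ 0.8), and BIC-selected Gaussian-mixture
  subgroup detection for bimodal proteins.
* **Signatures** — on the stable protein set: cohort z-scores, a linear
  profile per (individual, protein) giving baseline α, trend γ and
  fluctuation φ = Σ|residuals|, flags beyond ±3 SD of the population
  (Gaussian chance rate 2(1−Φ(3)) = 0.27% per criterion), per-individual
  and per-protein summaries, and inter-individual IQR diversity.

## Worked example

```r
library(longiplasma)

cohort <- simulate_cohort(sim_config(seed = 1))   # 101 x 4 x 200, duplicates
norm   <- normalize_pipeline(cohort$dataset)

stab <- classify_stability(inter_assay_icc(norm$dataset),
                           inter_visit_icc(norm$dataset))
stab
#> stability_report: 200 antibodies (ICC >= 0.80)
#>   technical 167/200 (84%), longitudinal 93/200 (46%), both 92/200 (46%)
```

So 84% of antibodies are technically consistent (duplicate assays agree),
46% are longitudinally stable (a person's level is reproducible across a
year), and 46% are both — the set worth scoring for personal signatures.
Module tracking and the deviation scheme continue from there:

```r
vm   <- modules_per_visit(norm$dataset)
core <- match_core_modules(vm)
core
#> core_module_assignment: 8 core patterns over 4 visits; 115/200 proteins assigned (57%)

stable <- stab$table$antibody[stab$table$class == "both_stable"]
pz     <- population_zscore(norm$dataset, stable)
flags  <- flag_deviations(profile_statistics(pz$z, pz$info))
flags
#> signature_flags: 9292 profiles; 1.54% flagged (chance 0.27% per criterion at +/-3 SD)
```

Every number above is checkable against the generator's ground truth
(`cohort$truth`): the 8 recovered core patterns are the 8 planted
modules (adjusted Rand index 0.97 per visit), the 2 seasonal flags are
the 2 planted sinusoids, all 15 planted cis-pQTLs are recovered as
significant cis top SNPs, and the flagged profiles include 24/24 planted
baseline deviants.

The `analysis/` directory holds numbered drivers
(`01_simulate.R` … `07_signatures.R`) that run these stages in order and
write their tables under `results/`. `run_pipeline()` does the same from
a single (YAML-able) configuration with a run manifest.

## Documentation

The methods vignette
(`vignettes/longitudinal-plasma-proteome-methods.Rmd`) describes the
generative model behind the synthetic cohorts, each stage's statistical
definitions and defaults, the numerical choices (fixed-point AbsPQN,
static tree cut, soft-power default), and known limitations.
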