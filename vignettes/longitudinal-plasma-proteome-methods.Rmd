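---
title: "Methods: longitudinal plasma proteome variability analysis"
author: "longiplasma"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal plasma proteome variability analysis}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`longiplasma` implements the analysis stages used to characterise the
variability of circulating plasma proteins measured repeatedly in the same
clinically healthy individuals with multiplexed antibody suspension bead
arrays (readout: median fluorescence intensity, MFI, per antibody per
sample). The stages are: per-plate normalization, intraclass-correlation
stability profiling, mixed-model trait and seasonal association scans,
per-visit co-expression module detection with cross-visit core-module
tracking, an additive cis-pQTL scan, and per-individual deviation
signatures. Because real cohorts of this kind are access-controlled, the
package ships a synthetic cohort generator with full ground truth; every
stage is validated against what was planted.

# The synthetic cohort generator

`simulate_cohort()` draws, for individual $i$, visit $t$, protein $p$ and
assay $a$, a log intensity

$$
y = \mu_p + \beta_p u_p g_{i} + b_{ip} + \gamma_{ip}\,t_\mathrm{yr}
  + s_p u_p \sin\!\left(\tfrac{2\pi d}{365.25} + \phi_p\right)
  + \lambda_p f_{m(p)}(i,t) + \mathrm{spike}_{ipt}
  + c_{ita} + \delta_{\mathrm{plate}(i,t,a),p} + \varepsilon,
$$

with raw MFI $= e^y$. The terms, their defaults, and what they emulate:

* $\mu_p \sim U(5, 9)$ — antibody-specific mean log MFI.
* $b_{ip} \sim N(0, \sigma_\mathrm{bio}^2)$, $\sigma_\mathrm{bio} = 0.5$ —
  individual-specific baselines, the dominant biological signal in healthy
  cohorts and the source of the person-specific signatures.
* visit-level biological noise with SD 0.05 for "stable" proteins and 0.5
  for a 40% "unstable" subset — the two tails of the longitudinal
  repeatability spectrum.
* $\varepsilon \sim N(0, \sigma_\mathrm{tech}^2)$ with
  $\sigma_\mathrm{tech} = 0.15$, raised to 0.5 for a 30% subset of
  antibodies — assay imprecision varies strongly across an antibody panel,
  and without this heterogeneity the technical/longitudinal classification
  is degenerate (every antibody technically perfect). The magnitudes are
  calibration choices on the log scale, not published values.
* $c_{ita} \sim N(0, 0.2^2)$ — per-assay sample scaling (dilution,
  labelling), multiplicative on the raw scale; the target of AbsPQN.
* $\delta_{\mathrm{plate},p} \sim N(0, 0.3^2)$ — per-(plate, antibody)
  shifts; the target of Multi-MA. Samples are randomized to 96-well plates
  within each assay batch, one batch per (visit, assay repetition),
  with near-equal plate fill.
* duplicate assays: every aliquot is measured twice by default, sharing
  all biology and redrawing only $c$, $\delta$, $\varepsilon$ —
  mirroring designs where complete sample sets are analysed in duplicate.
* modules: 60% of proteins load (loading $\lambda = 0.9$ on the log
  scale) on one of 8 latent trajectories, AR(1) across visits per
  individual with $\rho = 0.9$. Two deliberate choices sit here. First,
  $\rho$ is high: module expression is mostly a person-level trait that
  still co-varies over time; with $\rho \approx 0.5$ half the module
  variance falls within individuals and essentially every module protein
  becomes longitudinally unstable, which contradicts the observation that
  most module members are stable proteins. Second, $\lambda = 0.9$ gives
  within-module correlations near 0.7–0.75, the strength typical of
  lipoprotein-, complement- or platelet-driven plasma modules; much weaker
  modules are not recoverable by topological-overlap clustering with a
  fixed-height cut at panel sizes of a few hundred proteins.
* seasonality: 2 proteins carry an annual sinusoid of amplitude one
  population SD ($u_p$ is the protein's population SD of the log level,
  so all planted effect sizes are z-calibrated), keyed to the actual
  collection date; visits are quarterly with ±10 days jitter and
  individual start dates spread over a year.
* cis-pQTLs: 15 proteins receive an additive allele effect of 1.5
  population SD at a planted SNP (MAF 0.15–0.45, Hardy–Weinberg
  genotypes) positioned inside the protein-encoding gene's window; the
  rest of the panel is background SNPs.
* deviant profiles: 40 (individual, protein) cells each for persistent
  baseline offsets (±4 SD), linear trends (±4 SD/year) and single-visit
  spikes (±5 SD). Deviant proteins are drawn disjointly across the three
  criteria, and a planted baseline deviation *replaces* the individual's
  natural baseline and module trajectory rather than adding to them, so
  "a 4 SD deviant" means exactly that in the realized data; without the
  replacement the planted offset is confounded by the individual's own
  (random) baseline and the recovery rate of the flagging rule cannot be
  stated cleanly. 4 SD is the smallest planted offset for which a ±3 SD
  flag should have near-perfect sensitivity once the deviant's own
  contribution to the population SD is accounted for.
* traits: two traits are linked ($r = 0.9$) to designated proteins chosen
  among the longitudinally fluctuating ones — a random-intercept model
  identifies a protein–trait link mostly from within-individual
  co-fluctuation (the acute-phase situation), so linking a static protein
  would test nothing.

Counts are drawn by inclusion, so the ground truth matches the
configuration exactly. A protein's ground-truth "stable" designation is
derived from its theoretical inter-visit ICC (variance components of the
planted terms, duplicates averaged) at the 0.8 threshold.

What the generator does **not** emulate: antibody cross-reactivity,
bead-count QC, level-dependent (heteroscedastic) technical noise,
non-Gaussian biological distributions, missing visits, or correlated
trait panels. Passing the recovery tests therefore shows the pipeline is
correct under its stated model, not that real cohorts satisfy that model.

# Normalization

All analysis operates on natural-log MFI. Two plate-level artefacts are
removed, per 96-well plate, in this order:

1. **AbsPQN** (absolute probabilistic quotient): within a plate, the
   reference profile is the column-wise median; each sample's shift is
   the median over antibodies of its difference from the reference (the
   log of the classical probabilistic quotient). We iterate this
   median-shift step to its fixed point (tolerance $10^{-13}$, typically
   a handful of passes) rather than applying it once: the one-pass
   estimator leaves a residual of order $10^{-3}$ under re-application,
   while the fixed point makes the operation exactly idempotent, which is
   the natural definition of "the scaling has been removed". The block's
   pre-normalization grand median is restored afterwards so absolute
   levels are preserved (the "Abs" anchor). Factors are reported as
   $e^{q_i}$ in the audit.
2. **Multi-MA**: per antibody, plate means are equalized by
   $x \mapsto x - m_{\mathrm{plate}} + \bar m$, with $\bar m$ the
   unweighted mean of plate means. This is the closed form of the
   rotation-based multidimensional MA construction — the average (A)
   coordinate is preserved and the orthogonal difference (M) components
   are zeroed — and it removes a constant per-(plate, antibody) shift
   exactly.

The audit reports each antibody's between-plate variance share before and
after (one-way decomposition by plate). A caveat worth knowing: plate-mean
equalization estimates the shift from the ~96 samples on the plate, so it
also removes the plate's average biology; the distortion is of order
$\sigma_\mathrm{bio}/\sqrt{96}$ per antibody and is the reason the
noiseless-limit tests compare against log-transformed rather than
normalized data.

# Stability profiling

`icc_3_1()` is the two-way mixed-effects, consistency, single-measurement
intraclass correlation
$\mathrm{ICC}(3,1) = (MS_R - MS_E)/(MS_R + (k-1) MS_E)$. Technical
repeatability uses aliquots as targets and duplicate assays as raters;
longitudinal stability uses individuals as targets and visits as raters,
after averaging duplicates (keeping the two noise sources distinct) and
restricting to individuals with complete visits (the two-way layout needs
balance). Negative estimates are reported as computed. A protein is
classified on each axis at ICC ≥ 0.8 — a conventional "good reliability"
cut — giving four classes.

Identifiability is summarized two ways: per individual, ICC(3,1) with
cohort-standardized proteins as targets and visits as raters; and a
nearest-neighbour statistic (fraction of samples whose nearest other
sample in z-space belongs to the same individual; chance level
$(V-1)/(NV-1)$). Note a structural fact: with per-protein
standardization, the per-individual ICC is bounded near the
panel-average inter-visit ICC, so values like 0.99 are only attainable
when individual baselines dominate within-individual visit noise (or
when the statistic is computed on unstandardized data, where the
between-protein spread of mean levels inflates it). The package's
identifiability criterion is therefore exercised on the
baseline-dominated configuration.

# Trait and seasonal scans

Protein–trait associations use `lmerTest` random-intercept models
(protein ~ trait + covariates + (1 | individual), REML, Satterthwaite
degrees of freedom) — the standard longitudinal tool for this design —
with BH-FDR over the whole protein × trait grid and a significance flag
at FDR ≤ 0.001. Covariates default to none; sex/age/BMI can be listed.
Traits with fewer than 10 complete pairs, or constant traits, are skipped
with a warning.

The seasonal scan fits the annual first harmonic
$y \sim b_s \sin(2\pi d/365.25) + b_c \cos(2\pi d/365.25) + (1|\,i)$ with
$d$ the day of year, tests $(b_s, b_c)$ jointly by a 2-df likelihood
ratio between ML fits, and flags at FDR < 0.01. Amplitude is
$\sqrt{b_s^2 + b_c^2}$, phase $\mathrm{atan2}(b_c, b_s) \in [0, 2\pi)$.
Collection dates must span at least six months, otherwise the phase is
unidentifiable and the scan refuses to run.

# Co-expression modules and core patterns

Per visit, on the individuals × proteins matrix (duplicates averaged):
unsigned adjacency $a_{ij} = |\mathrm{cor}|^\beta$, topological overlap
$\omega_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$,
average-linkage clustering on $1-\omega$, a static cut at height 0.8,
minimum module size 10, module eigengenes (first principal component of
the standardized member matrix, unit variance, oriented to correlate
positively with members), and iterative merging of modules whose
eigengenes correlate above 0.8. The static cut was chosen over the
dynamic hybrid cut for determinism and testability.

The soft power default is 2 in the per-visit wrapper. The scale-free
criterion (`pick_soft_power()`, smallest $\beta$ with fit $R^2 \ge 0.8$
of $\log p(k)$ on $\log k$) is implemented and exported, but it targets
transcriptome-scale networks; on panels of a few hundred proteins with
strong modules it drives $\beta$ high enough to crush the topological
overlap below any fixed cut height, so the wrapper prefers the low power
that preserves TOM contrast. Both knobs are arguments.

Core patterns track module membership across visits: modules of
consecutive visits are matched one-to-one by maximal Jaccard overlap of
membership sets (greedy, descending overlap; ties to the larger
earlier-visit module, then the lower label), chains spanning every visit
define candidate patterns, a protein is assigned only if it sits in the
chain's module at every visit, and patterns with fewer than 5 members are
dropped. Matching operates on membership sets, so module numbering is
irrelevant. Core-pattern eigengenes are tested against traits per visit
(linear regression for continuous, one-way ANOVA for categorical traits)
with BH-FDR over the whole grid at FDR < 0.01.

# cis-pQTL scan

Genotype QC removes SNPs with MAF < 0.05 or a 1-df chi-square
Hardy–Weinberg p below $10^{-6}$. The GWAS phenotype is the
across-visit mean of normalized log levels per individual — the
construction that maximizes repeatability; a single-visit option exists.
Each antibody is regressed on each dosage (additive OLS; the scan is
vectorized through correlation algebra and matches per-SNP `lm()` to
$10^{-10}$), with Bonferroni control $\alpha/M$ over the $M$ SNPs
actually tested. Top SNPs are annotated as cis when they fall within the
protein-encoding gene's window ± 1 Mb (configurable down to 0), and
their LD proxies ($r^2 \ge 0.8$, genotypic squared correlation) are
reported. Subgroup detection for bimodal protein levels fits 1- vs
2-component Gaussian mixtures (`mclust`, equal- and unequal-variance
families) and selects by BIC; this is a documented stand-in for however
such subgroups are called by eye in practice.

# Individual deviation signatures

On the `both_stable` protein set (the scoring focuses on precisely
measured profiles), proteins are z-scored over all samples of all
individuals. Per individual and protein, an OLS line against time in
years (centered per individual, computed from actual collection dates
because inter-visit spacing varies) yields baseline $\alpha$ (level at
the individual's mean time), trend $\gamma$ (SD/year) and fluctuation
$\phi$ (sum of absolute residuals; exactly 0 for a linear profile).
Individuals need at least 3 visits. For each protein and statistic, an
individual is flagged when its value lies more than $k = 3$ SD from the
across-individual mean (mean and SD include the tested individual — the
closest literal reading; a single extreme individual therefore inflates
the SD slightly and masks, which is why planted deviations are sized at
4 SD and above). The Gaussian chance rate per criterion is
$2(1-\Phi(3)) = 0.27\%$; since it is ambiguous whether such a figure
refers to one criterion or the union of three, both are reported
(union under independence ≈ 0.81%). $\phi$'s null is not Gaussian, so
its flag rate is reported separately and is expected above 0.27%.

Inter-individual diversity is the IQR across individuals of each
protein's mean z-score, with illustrative cut-offs at ≤ 0.15
(low diversity) and ≥ 1.5 (high). Two distributional facts matter when
reading these: with $V$ visits and no individual signal the expected IQR
is about $2\Phi^{-1}(0.75)/\sqrt{V} \approx 0.67$ at $V = 4$; and for a
z-scored Gaussian protein the all-between-individual limit is
$2\Phi^{-1}(0.75) \approx 1.35$ — the ≥ 1.5 regime is therefore reached
only by heavy-tailed or bimodal level distributions, e.g. the
genotype-split proteins, not by Gaussian baselines however strong.

# Numerical and procedural choices

* Mixed models come from `lmerTest` (Satterthwaite df) rather than a
  bespoke REML implementation; at ~400 observations per fit the
  difference from residual-df Wald tests is negligible, and using the
  field's standard fitter makes results comparable.
* BH-FDR is `stats::p.adjust(method = "BH")`, checked in the tests
  against a brute-force step-up oracle.
* ICC estimation drops incomplete rows (complete-case per analysis);
  a pairwise option is out of scope.
* Determinism: one integer seed drives the generator; all downstream
  stages are deterministic given the data (mixture fits use mclust's
  deterministic model-based initialization), so `run_pipeline()` with an
  identical configuration reproduces byte-identical tables.
* Problem sizes in the shipped tests and acceptance script: unit tests
  run 30–60-individual cohorts with 40–60 proteins; the end-to-end
  checks use the full 101 × 4 × 200 default, 100 replicate genotype
  panels of 10,000 SNPs for the detection-rate estimate, and three
  default cohorts pooled for the deviation-sensitivity estimate. These
  sizes give stable Monte-Carlo estimates for the stated thresholds.

# Known limitations

* The exact reference formulations of AbsPQN and Multi-MA in the
  originating assay literature live in supplementary material that is not
  redistributed; the implementations here are the standard PQN in log
  space with an absolute anchor, and the exact closed form of plate-mean
  equalization, both documented above as swap points.
* The chain-construction rule for core patterns (greedy maximal Jaccard)
  is one reasonable realization of "sequential overlap matching"; other
  rules (e.g. optimal assignment) could assign slightly different
  fractions.
* Complete-case handling of missing visits is the default everywhere;
  real cohorts with informative missingness need care the package does
  not provide.
* The per-individual ICC bound under standardization (see above) means
  published unstandardized identifiability figures are not directly
  comparable to this package's standardized statistic.
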