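---
title: "Label-free LC-MS peptidomics: models, normalization and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free LC-MS peptidomics: models, normalization and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpep)
```

# The problem

Endogenous peptides (neuropeptides, granin fragments, propeptides) are
quantified label-free: chromatographic ion intensities of matched peptide
peaks are compared across LC-MS runs. Run-to-run intensity is not comparable
out of the box — the injection sequence drifts, each run carries its own
multiplicative and additive scale distortion, and low-abundance peptides
drop below the detection limit more often than abundant ones, so missingness
is informative (missing not at random, MNAR).

`lfqpep` implements the complete analysis chain for such a study on a
randomized block design with two ages, two sexes and a treatment factor
(eight experimental groups), an interspersed technical-replicate reference
sample, and a catalog of identified peptides: normalization, multivariate
class modelling, and per-peptide factorial inference, plus a peptide
mass/cleavage toolkit and a synthetic-data generator that provides ground
truth for every stage.

# Peptide toolkit

`monoisotopic_mh()` sums monoisotopic residue masses plus one water and one
proton, with canonical (Unimod) deltas for phosphorylation (+79.96633 Da),
C-terminal amidation (−0.98402), N-terminal pyroglutamate from Q (−17.02655),
methionine oxidation (+15.99491) and N-terminal acetylation (+42.01057).
Identification tables from ion-trap instruments print low-resolution
*observed* masses; several catalog entries differ from theory by 0.1–0.8 Da,
so only entries agreeing with theory within 0.01 Da serve as numerical
anchors in the tests.

`find_cleavage_sites()` scans precursors for the prohormone-convertase
motifs: all four dibasic pairs {KK, KR, RK, RR} (cleavage after the pair) and
the RxnR motif with exactly n ∈ {2, 4, 6} intervening residues (cleavage
after the final R). The literature sometimes restricts dibasic scanning to
KR/RR; we scan the superset and report the matched pair so callers can
filter — a superset is safe and filterable. `enumerate_candidate_peptides()`
returns the maximal segments between dibasic motifs in 0-based half-open
coordinates; the candidates plus motif spans tile the precursor.

```{r}
monoisotopic_mh("YGGFMRF")      # Met-enkephalin-Arg-Phe
find_cleavage_sites("AAKRSGKLSFLEDEMRRAA")
```

# The data model

A `DesignTable` holds one row per run: run order, sample id, age
(`ed12`/`ed17`), sex (`M`/`F`), treatment (`C`/`E`), block, and a
reference-replicate flag. Validation enforces that run order is a
permutation, non-reference samples occur once, and all reference runs share
one sample id. An `intensity_matrix` is a peptides × runs grid of log2 ion
intensities with explicit `NA` for missing entries — zero is a legitimate
log2 intensity, so blanks, never zeros, encode missingness — and a vector of
state flags (`log2` → `calibrated` → `drift_corrected` → `filtered` →
`collapsed`) that enforces the pipeline order. Group labels are always
derived from the factors, never stored, so labels cannot drift from the
design.

# Two-step normalization

**Calibration.** A reference ("median") run holds, for every peptide matched
in strictly more than 50% of runs, the median of its observed log2
intensities. Each run is regressed on this reference over their shared
peptides (`observed = a + b·reference`, ordinary least squares) and mapped
onto the reference scale by `(v − a)/b`. The direction of the original
regression is not recoverable from a methods text that says runs were fitted
"to a median run" with "new values predicted"; we therefore commit to the
*outcome* as the contract: after calibration, re-fitting any run against the
reference yields slope 1 and intercept 0 to 1e−8, and the transform is
idempotent. Runs need ≥ 3 shared peptides; |b| < 1e−6 is a degenerate-run
error.

**Drift correction.** For each peptide, a locally-weighted linear regression
(lowess) of intensity on run order is fitted and subtracted. The smoother is
pinned precisely because "lowess" alone underdetermines the estimate: at each
observed run the nearest ⌈span·n_obs⌉ observed runs enter a degree-1 weighted
least squares with tricube distance weights and **no** robustness
iterations; span defaults to 0.5 of that peptide's observed runs. A
per-point weighted-OLS oracle in the tests makes this choice explicit and
checkable. The mean of the fitted trend is added back so the peptide keeps
its native intensity level; adding the fitted-trend mean (rather than the raw
mean) preserves the per-peptide mean of observed values exactly. Peptides
with fewer than 4 observations are left uncorrected and flagged. A pure
linear drift is removed exactly (a local linear fit reproduces a global
line); on simulated sinusoidal drift of amplitude 1.0 log2 units with a
period exceeding the span window, the residual correlation between corrected
values and the true drift stays below 0.2.

**Outlier flagging.** Runs whose median observed intensity falls more than
`k` MAD-scaled deviations below the cohort median of run medians are flagged
(default k = 3). Flagging is advisory: the pipeline exposes two drop points
(a configured pre-normalization list, mirroring removal of a degraded
sample, and the post-flagging drop) because outlier handling is a judgment
call the caller owns. A "too many peaks / degradation" criterion has no
algorithmic definition and is supported only via the configured drop list.

**Filtering and collapsing.** The minimum-matching filter keeps a peptide
only if every group misses it in at most one run (`max_missing_per_group =
1`). Technical replicates of the reference sample are collapsed to one
pseudo-run holding the per-peptide median over observed replicates (present
iff any replicate observed it). No stage ever imputes: missing stays
missing.

# Multivariate class models

PCA and PLS-DA follow the conventions of the SIMCA-era modelling software
the field used:

* Variables are centered and scaled to unit variance by default (`scale =
  "uv"`); the original analysis software's scaling is undocumented in the
  methods we emulate, so a `"center"`-only flag records the uncertainty.
* Components are extracted sequentially by NIPALS; PCA scores/loadings agree
  with an SVD oracle to 1e−8 up to sign. Eigenvalues are reported as
  (n−1)·var(score); printed eigenvalues in legacy software use unstated
  normalizations and are not comparable across tools.
* **Q2** comes from K-fold cross-validation (default 7 folds, the
  conventional default of that software) assigning whole observations to
  folds in row order — simpler and more transparent than element-wise CV,
  which the methods text does not specify. Per fold, the model is refit on
  training rows; held-out rows are projected on the training loadings
  (PCA: reconstruction PRESS; PLS-DA: Y-prediction PRESS);
  `Q2_a = 1 − PRESS_a / SS_{a−1}` with cumulative Q2 from the product rule.
* **Diagnostics**: Hotelling T² per observation with its 95% F-referenced
  tolerance limit `A(n²−1)/(n(n−A))·F₀.₉₅(A, n−A)`, and DModX — the
  normalized residual standard deviation — with the critical distance at
  significance 0.05 from the F distribution on `(p−A, (n−A−1)(p−A))` degrees
  of freedom. Training-set leverage corrections are not applied; the limits
  are reference lines, not tests.
* **PLS-DA** regresses X against the column-centered K-class indicator
  matrix by the two-block NIPALS algorithm (the weight vector converges to
  the dominant eigenvector of X'YY'X), deflating X and Y per component;
  predicted class is the argmax over dummy columns. Every CV training fold
  must contain every class.
* **VIP**: `VIP_j = sqrt(p · Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a)`; the mean
  of squared VIPs is 1 by construction, making VIP > 1 the natural
  relevance threshold. Confidence intervals come from leave-one-observation-
  out jackknifing with the standard-error form (point ± t₀.₉₇₅,ₙ₋₁ · SE,
  SE² = (n−1)/n · Σ(vipᵢ − v̄)²), not percentile intervals — the standard
  choice at these sample sizes and exactly reproducible by a brute-force
  loop.

The group-median transform (`Xclass − Xtot`: group median minus the
peptide's overall median) feeds two-way hierarchical clustering with
complete linkage on Euclidean distances (via `stats::hclust`, checked
against a brute-force O(n³) agglomeration oracle), exported as Newick.

Because no stage imputes, the multivariate stage uses the complete-case
peptides (no missing entry after collapsing). The filter guarantees at most
one missing run per group, so this retains the majority of peptides; the
alternative — NIPALS with missing-value skipping, as legacy software did —
trades transparency for coverage and is out of scope.

# Factorial differential expression

Each peptide's normalized log2 intensity is fit by ordinary least squares to
the full fixed-effects 2×2×2 model — age, sex, treatment and all
interactions — with sum-to-zero contrasts, using that peptide's complete
cases (the filter keeps designs near-balanced). "Marginal sums of squares"
is read as Type III: the SS increase from deleting a term's columns from
the full model, which the tests verify against independent full-vs-reduced
comparisons and `car::Anova(type = "III")`. The overall F tests the full
model against intercept-only and is adjusted across peptides by
Benjamini–Hochberg (the standard FDR step-up; Benjamini–Yekutieli is
available behind a flag). The joint interaction test is the nested-model F
comparing the full model to main-effects-only — identical to the Wald F for
the joint linear hypothesis under OLS. Least-squares means are averages of
the model's cell-mean predictions over the 2×2×2 grid (checked against
`emmeans`); fold changes are the level-mean contrasts ed17−ed12, F−M, E−C —
signed so that an ed17-upregulated peptide has a positive age fold change
and a treatment-suppressed peptide a negative treatment fold change.
Pairwise t statistics use the model residual variance with exact contrast
standard errors, tiered at p < 0.05 (*), < 0.01 (**), < 0.001 (***).
Unestimable peptides (a factor level entirely missing), saturated fits
(zero residual df) and constant peptides are flagged, never fatal.

Blocks are not modeled as random effects: the emulated analysis used a
fixed-effects model only, and the randomized block design enters through
the run-order randomization instead.

# The synthetic-data generator

`sim_config()` defaults to the `study2010` preset: 204 peptide ions × 42
runs, group sizes (5,5,5,4,4,4,4,5), five blocks, six technical-replicate
reference runs (one opening each block, one closing the sequence). Each
entry is

```
value(p, r) = baseline_p + Σ effects via group membership
            + slope_r · (baseline_p − mean baseline) + intercept_r
            + drift(run_order_r) + ε,   ε ~ N(0, noise_sd²)
```

followed by MNAR deletion with probability
`floor + (1 − floor)·plogis(−(value − midpoint)·steepness)`. Effects are
half-coded so a planted effect equals the level-mean difference; the
generator is a pure function of its seed and never touches the caller's RNG
stream.

The emulated study does not quantify drift amplitude, per-run scale spread,
residual noise or missingness rates, so the defaults are stated assumptions,
chosen once as typical for ion-trap label-free data of that era and
documented here rather than in any result: baseline N(16, 2.5²) log2 units
(identified peptides in such data span roughly 12–19), sparse effects
dominated by age (25% of peptides with an N(1.5, 1²) ed17−ed12 shift — mostly
upregulation at the later age — against 5% each for sex, treatment and the
age×treatment interaction), sinusoidal drift of amplitude 0.5 over the run
sequence, per-run slope sd 0.05 and intercept sd 0.5, residual sd 0.3, and a
logistic MNAR with midpoint 10, steepness 1.5 and floor 0.01 (≈ 2% overall
missingness, concentrated in low-abundance peptides — the regime in which
the ≤ 1-missing-per-group filter retains most peptides, as it did in the
emulated study). MNAR rather than MCAR is deliberate: label-free missingness
is intensity-dependent; steepness 0 degrades gracefully to MCAR.

What the generator does **not** emulate: chromatographic peak shapes,
retention-time alignment errors, correlated peptides from shared precursors,
heavy-tailed noise, and batch-structured (rather than smooth) run effects.
Passing recovery tests on this generator therefore demonstrates that the
*statistical pipeline* is correct under its own assumptions, not that those
assumptions exhaust real LC-MS data.

# Identifiability under global calibration

Calibrating every run against a median reference run assumes most peptides
are stable across runs. When the true effect distribution is asymmetric
(many peptides up at the later age), the per-run intercept absorbs the
run-average biological shift, so the estimable quantity per peptide is its
effect **relative to the average peptide**, and apparently "null" peptides
acquire a small opposite-sign relative effect. This is a property of all
global intensity normalization, not of this implementation; the analysis
scripts therefore judge end-to-end recovery against mean-centered truth,
while the statistical-engine recovery tests (no run distortion, hence no
calibration) use absolute truth. Interpret pipeline fold changes
accordingly: they are relative to the cohort-average peptide behaviour.

# Numerical choices and problem sizes

Tolerance pins: NIPALS convergence 1e−10 (max 500 iterations), calibration
contract 1e−8, lowess-vs-oracle 1e−8, VIP identity 1e−10, jackknife-vs-loop
1e−10, Type III SS vs model comparison 1e−8. Component signs are fixed so
the largest-magnitude loading/weight is positive. Ties in clustering follow
`hclust`'s deterministic merge order. Degenerate inputs (zero-variance
variables under unit-variance scaling, < 3 shared calibration peptides,
groups lost from CV folds, zero pooled variance with nonzero difference)
raise named errors or flags rather than silent results.

The test suite and the reproduction script run: the full 204 × 42 study
(seconds), planted-effect recovery with 200 peptides × 32 runs over 5 seeds,
a 50-seed global-null error-control study, and 15–40-seed property checks
for Q2 and VIP behaviour — sizes chosen so every stochastic claim is backed
by enough replicates to be stable under its fixed seed while the whole suite
stays fast.

# Known limitations

* No raw-spectrum processing, peak detection or matching: the pipeline
  starts from an exported intensity matrix.
* No imputation, and the multivariate stage is complete-case.
* No mixed/random-effects modelling of blocks, and no empirical-Bayes
  variance moderation.
* Legacy-software outputs that depend on the lost raw data of the emulated
  study (its printed R2X/Q2/eigenvalues and per-peptide VIPs) are not
  reproducible and are not treated as targets; the pipeline reports the same
  *kinds* of quantities computed from its own inputs.
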