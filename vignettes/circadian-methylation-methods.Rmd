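---
title: "Methods: detecting circadian cytosine-modification oscillations and their aging associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting circadian cytosine-modification oscillations and their aging associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscmod)
```

This vignette documents the statistical models implemented in `oscmod`, the
conventions and numerical choices behind them, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## Data model

The raw observable is a pair of integer matrices: methylated (`M`) and
unmethylated (`U`) read counts per CpG site and sample. A *sample* is one
sequencing library, identified by (biological sample, technical replicate
index, assay). The assay is either standard bisulfite (`BS`), which reads
total modification (5mC + 5hmC, "modC"), or oxidative bisulfite (`oxBS`),
which reads only true 5-methylcytosine ("mC"). Each biological sample is one
animal killed at a known Zeitgeber time (ZT; hours after light onset in a
12:12 light–dark cycle). Because collection runs longer than 24 h, the
absolute collection hour and its wrapped ZT are stored separately; all
harmonic models see only ZT mod 24.

Modification density is the β-value, β = M/(M+U), computed per cell after a
coverage filter: a site is kept only if every sample covers it with at least
30 reads (`filter_min_coverage()`, boundary inclusive). At 30+ reads the
binomial standard error of β is at most ~0.09, and around 1,800× — the
depth this design targets — it is ~0.012, which is what makes amplitudes of
3–5% resolvable at all. Cells with zero coverage are missing, never zero.

Sample-level QC (`remove_outlier_samples()`) computes all pairwise Pearson
correlations between samples on pairwise-complete sites, averages them per
sample, and drops samples more than 3 SD below the mean of those averages.
This is a single pass — the threshold is not re-estimated after removal — and
zero-variance samples are flagged rather than silently scored. Note that a
single grossly aberrant sample inflates the SD of the per-sample means, so
with few samples (≈10) even a perfectly anti-correlated sample may not cross
3 SD; the screen is designed for the study-scale regime of ~30+ samples per
tissue × age group.

## Epigenetically variable cytosines

Technical replicates measure the same DNA, so their spread estimates assay
noise. `detect_evc()` runs, per site and per tissue × age group, a one-way
fixed-effects ANOVA with biological sample as the grouping factor:
F = MS~between~/MS~within~ with (k−1, N−k) degrees of freedom. Sites with
p < 0.05 are EVCs — sites where animals genuinely differ beyond assay noise —
and only EVCs enter rhythm, phase and aging analyses. Missing cells are
dropped; a biological sample contributes only if it retains ≥2 replicates at
the site. Two degenerate cases are reported explicitly rather than silently:
zero within-group variance with distinct group means (p = 0, flag
`degenerate`) and an all-constant site (p = 1, flag `constant`). After EVC
selection the replicates are collapsed by their median (midpoint for even
counts), one robust value per biological sample.

EVC status is nominal (α = 0.05, no FDR) by design: the EVC screen is a
variance filter, not an inference endpoint, and downstream permutation tests
quantify experiment-level significance on the filtered set.

## Harmonic regression

Rhythmicity is modeled by ordinary least squares on a fixed 24 h period:

$$y = b_0 + b_1\sin\!\left(\tfrac{2\pi\,\mathrm{ZT}}{24}\right)
        + b_2\cos\!\left(\tfrac{2\pi\,\mathrm{ZT}}{24}\right) + \varepsilon$$

The test is the F-comparison against the intercept-only model (df 2, n−3).
Derived quantities are the peak-to-trough amplitude $A = 2\sqrt{b_1^2+b_2^2}$
and the acrophase $\phi = \frac{12}{\pi}\,\mathrm{atan2}(b_1, b_2) \bmod 24$,
the ZT at which the fitted curve peaks. The design matrix is shared across
sites and solved once by QR (`harmonic_fit_matrix()`), so 10⁴ sites fit in
well under a second; rows with missing cells fall back to individual
complete-case fits and require ≥4 distinct ZT values. A constant series gets
p = 1, amplitude 0 and an undefined (missing) acrophase. Acrophases in
[0, 12) are *sleep* phases (lights on, nocturnal animals asleep) and [12, 24)
*wake* phases; the intervals are half-open so ZT12 is counted exactly once,
as wake.

Fitting requires no sequential sampling: the same machinery serves period
scans (R² profiles over candidate periods, e.g. actogram spectra), PCA
component scores, chromosome-wide means, and gene-expression time courses.

## Permutation nulls

Per-site p-values say little about an experiment-wide rhythm, so the
mean-R² permutation test (`permute_mean_r2()`) shuffles the ZT labels of the
samples — one shuffle applied jointly to all sites, preserving the inter-site
correlation structure — and recomputes the mean harmonic R² over EVCs. The
p-value is the fraction of permutations whose statistic strictly exceeds the
observed; zero exceedances are reported as "< 1/n_perm". Two numerical
choices matter here. First, exceedance uses a 10⁻¹² tolerance: a permutation
whose statistic is *analytically* equal to the observed one (time reversal,
for instance, leaves every R² unchanged) must not flip between "tie" and
"exceedance" on floating-point noise. Second, for ≤8 samples the test can
enumerate all n! relabelings (`exhaustive = TRUE`), which the test suite
checks against an independent `lm()`-based enumeration.

The acrophase-difference test (`median_acrophase_diff_test()`) works the
same way on the median minor-arc difference — the shortest distance between
two clock times on the 24 h circle, in [0, 12] — permuting the pairing of one
acrophase set against the other.

## hmC estimation and the antiphase analysis

hmC is estimated by subtraction, hmC = β~BS~ − β~oxBS~, on biological-sample
collapsed matrices aligned site-by-site, restricted to the union of modC and
mC EVCs. Negative estimates are retained: the subtraction estimator is
unbiased, and clamping at zero would bias low-hmC sites upward; a `clamp`
flag exists for display. The mC/hmC antiphase analysis fits both matrices,
keeps sites whose harmonic fit is significant in *both* modalities (a
noisy, non-significant fit has an essentially random acrophase that drags
the median difference toward 6 h), and tests the median minor-arc difference
against the pairing-shuffle null with the `greater` alternative.

In the generator, antiphase partners are built by giving the hmC component
twice the modC amplitude, in phase with modC; the residual mC = modC − hmC
then oscillates in exact antiphase with hmC, and the planted minor-arc
difference is exactly 12 h.

## The mRNA phase-shift scan

For each gene, the mean β of its (EVC) sites per sample forms the
modification profile x. The gene's mRNA time course is summarized by its own
harmonic model, evaluated at the modification sampling times shifted by
p = 0, …, 23 hours (ZT − p; the curve moves p hours later), and Pearson-
correlated with x; the scan statistic r~p~ averages over genes. Because the
evaluated curve is a pure sinusoid about its mesor, the scan is exactly
antisymmetric, r~p+12~ = −r~p~ — a property the tests assert to 10⁻¹².

A consequence worth spelling out: if a transcript's peak precedes the
modification *nadir* by k hours (expression first, demethylation bottoming
out k hours later), then shifting the mRNA curve k hours later aligns its
peak with the nadir and produces the strongest *anti*-correlation at shift
k — and, by antisymmetry, the strongest positive correlation at k + 12. The
scan therefore reports `lag_estimate` (the argmin of r~p~, i.e. the
expression-to-nadir lag) alongside `peak_shift` (the argmax). The generator
plants mRNA acrophases at (nadir − lag) mod 24, and the recovery tests
assert `lag_estimate` equals the planted lag. The null shuffles, jointly per
permutation, the ZT labels of the modification samples and the
gene-to-profile pairing; per-shift p-values are Bonferroni-corrected by the
24 shifts. Genes whose mRNA model is flat (no phase) or whose modification
profile has zero variance are excluded and counted.

## Aging regression and association battery

Age-correlated sites are found by per-site OLS of β on age in months across
the cohorts (9, 15, 25; age is numeric, not categorical), F-tested against
the intercept-only model and Bonferroni-corrected over the tested universe —
the EVCs shared by all three age groups. The slope sign gives the direction
(gain/loss of modification with age). The "magnitude of the aging effect" is
operationalized as |b₁| × 16 months, the modeled total change over the
study's age span; any monotone transform of |b₁| gives the same correlation
sign, and the span factor keeps the quantity in interpretable β units.

The association battery is deliberately plain:

* `fisher_association()` — two-sided Fisher exact test on the 2×2 membership
  table over a common universe; the reported OR is the sample odds ratio
  (a·d)/(b·c) with a Woolf logit 95% CI, adding 0.5 to every cell only when
  some cell is zero. Degenerate margins are flagged and the OR withheld.
  (The conditional-MLE OR of `fisher.test` is a reasonable alternative; the
  sample OR is reported because it is the conventional summary alongside
  Woolf intervals.)
* `acrophase_direction_asymmetry()` — among sites both oscillating and
  age-correlated, the sleep/wake × gain/loss table.
* `venn_binomial_enrichment()` — oscillation calls from the three age
  groups partition into 7 Venn regions; each region's age-modC count is
  tested against the expected proportion (the age-modC fraction among all
  universe sites) with the exact two-sided binomial test. Two-sidedness
  follows the minimum-likelihood convention of `binom.test`, not a doubled
  single tail. The baseline universe is configurable; the default (all
  tested EVCs) is the conservative choice.
* `weighted_pearson()` — for gene-level transcript comparisons, weighting by
  the number of cytosines per gene; the p-value uses a t approximation with
  Kish's effective sample size (Σw)²/Σw² in place of n, since weights here
  reflect measurement multiplicity rather than replication.

## The synthetic-data generator

`simulate_experiment()` generates count-level data under the study's
design, with every planted parameter exported in `truth`. Defaults are the
study conditions: a 2 h grid over 58 h (30 collection times), three cohorts
of 12/10/10 biological samples at 9/15/25 months, technical triplicates,
Poisson read depth with mean 1,800 (floored at 10), binomial methylated
counts. Site-level structure: Beta(20, 20) baselines; an oscillating
fraction (default 0.35) with truncated-normal peak-to-trough amplitudes
(mean 0.045, SD 0.022, truncated to [0.005, 0.17] — realized moments follow
the truncated distribution, which the tests check in closed form); gene-block
acrophases from a two-component von Mises mixture centered at ZT6 and ZT18
(κ = 2) with 0.5 h per-site jitter, so sites within a gene share phase the
way neighboring CpGs do; per-biological-sample Gaussian noise (SD 0.01) on
the latent density, shared between the BS and oxBS assays of the same
animal.

Aging structure: an overall aging fraction (default 0.15) whose membership
odds are 4-fold higher at oscillating sites (`aging_osc_odds`; the per-class
probabilities are solved to preserve the overall fraction). Slope magnitudes
are truncated-normal with mean 0.003 β/month — about a 5% modification
change over the 16-month span. This scale is chosen so that Bonferroni-level
detection remains possible at oscillating sites, whose residual variance
includes the oscillation itself; with much smaller slopes the aging test
sits on its detection cliff exactly where oscillation inflates the residual,
and the measured overlap inverts regardless of the planted membership
association. Even at this scale the measured odds ratio is attenuated
relative to the planted 4 (differential power), which is itself an
instructive property of the design. Slope signs follow the
sleep-gain/wake-loss rule with probability `acrophase_aging_coupling`
(default 0.9), and slope magnitude shares a latent Gaussian with the
amplitude draw (`amplitude_aging_corr`, default 0.6), planting the
amplitude–magnitude correlation; truncation attenuates the realized
correlation to ≈0.53.

`simulate_expression()` adds matched mRNA time courses: genes containing
oscillating sites get a sinusoid whose acrophase precedes the gene's
modification nadir by `mrna_lag_hours`, others are flat; Gaussian noise
everywhere.

What the generator does **not** emulate: probe-capture and sequence-context
coverage bias, bisulfite conversion failure (a 0.006 inflation toward 1 is
available but off by default), cell-composition changes that could mimic
oscillations, spatial correlation of methylation beyond shared gene-block
phase, non-sinusoidal waveforms, and read-level artifacts (PCR duplicates,
mapping). Passing recovery tests on this generator therefore demonstrates
that the inference stack is correct and calibrated for the assumed noise
model — binomial counting plus Gaussian biological variation — not that real
tissues satisfy that model.

## Problem sizes and numerical choices

The test suite runs the calibration checks at 10,000 null series (type-I
bands [0.041, 0.059] around α = 0.05), parameter recovery at 400 sites × 30
timepoints × 1,800× depth, antiphase recovery at 300 sites, lag recovery at
250 sites per lag, CI coverage of the asymmetry OR over 200 replicates of
400 sites, and ten full null-pipeline replicates — sizes chosen to make
Monte-Carlo error small relative to each tolerance while keeping the whole
suite around a minute of compute. Exhaustive permutation oracles run at 4–5
samples/pairs (24–120 relabelings). The Fisher oracle enumerates every 2×2
table with total ≤ 40 against the hypergeometric distribution.

Other conventions collected in one place: OLS via QR throughout (stable for
near-collinear grids); min-max bin normalization maps zero-range bins to
0.5; BED intervals are 0-based half-open and sites analyzed as captured (no
strand merging); permutation p-values are n_exceed/n_perm with the strict-
greater convention and the 10⁻¹² tie tolerance; all stochastic functions
take explicit seeds, and `sim_config(seed = )` makes the entire experiment
byte-reproducible.

## Limitations

Only the fixed-period sinusoidal model is implemented — no JTK_CYCLE-style
nonparametric detection and no multi-harmonic waveforms, so non-sinusoidal
rhythms lose power. Oscillation calls are nominal-α by design, matching the
permutation-backed workflow, and should not be read as FDR-controlled site
lists. The aging model is linear in age with three support points; monotone
but saturating trajectories will load on the linear term with reduced
effect size. hmC subtraction compounds the noise of two assays, so hmC
analyses need either depth or site-set restriction (the EVC-union rule) to
be informative. Finally, the package analyses bulk tissue: rhythmic cell
composition changes are a confound the statistics cannot exclude — the
appropriate control (cell-specific non-circadian markers) is experimental,
not computational.
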