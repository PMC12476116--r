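---
title: "Methods: permutation inference and spatially-aware annotation of inflammation–brain maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation inference and spatially-aware annotation of inflammation-brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`inflamap` implements a complete analysis chain for relating a serum
inflammation marker (C-reactive protein, CRP) to brain imaging
phenotypes and their molecular and behavioral annotations. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## The fALFF measure

A voxel's BOLD time course is linearly detrended, Fourier transformed,
and summarized as the fractional amplitude of low-frequency
fluctuations: the sum of spectral amplitudes over bins with
`f_low <= f <= f_high` divided by the sum over all positive-frequency
bins up to Nyquist, with the DC bin excluded from both sums. The raw
ratio lies in [0, 1], is invariant to rescaling of the series, and is
monotone in the band. The subject map is then divided by its in-mask
mean, so standardized maps have global mean 1.

Parameters: `band` (Hz; default 0.01–0.1, the conventional
low-frequency window), `tr` (s), `spectrum` (`"amplitude"`, the square
root of power, the usual convention for this measure; `"power"`
available because descriptions of the ratio vary between the two), and
`detrend`. Detrending prevents slow drifts from loading on the band,
but it also leaks a small fraction of a pure in-band tone's energy
across bins (a 0.05 Hz unit tone scores ≈ 0.92, not 1.0); the
analytic single-bin identities therefore hold exactly only with
`detrend = FALSE`, and the tests assert them that way. Constant series
have an undefined ratio and are defined as 0 with a warning flag. No
taper is applied: with no guidance favoring a window, the plain
transform is the most reproducible choice.

## Voxel-wise inference

`fit_voxelwise_glm()` fits, per voxel, an ordinary least squares model
with an intercept, the regressor of interest (log CRP in the pipeline)
and nuisance covariates (age, sex, education, and frame-wise
displacement for fALFF; age, sex, education for diffusion metrics),
returning the t statistic of the interest coefficient with
`df = n - rank(design)`. The design is checked for full rank and
collinear columns are named in the error.

Permutation inference uses the Freedman–Lane scheme: the reduced
(nuisance-only) model is fitted once, its residuals are permuted, the
nuisance fit is added back, and the full-model t map is recomputed.
Because the interest regressor is residualized against the nuisance
block, each permutation reduces to cross products, which keeps
thousands of permutations cheap.

* **Cluster-extent FWE** (`cluster_fwe()`): clusters form at the
  one-sided threshold `qt(1 - cluster_p, df)` separately for positive
  and negative contrasts (default `cluster_p = 0.001`), with 26-neighbor
  connectivity (6 available). Each observed cluster's corrected p is
  `(1 + #{null max extent >= size}) / (n_perm + 1)`, the >= convention
  counting ties conservatively. Peak coordinates are reported as
  1-based voxel indices: synthetic grids carry no template registration,
  which is deliberately out of scope.
* **TFCE FWE** (`tfce_fwe()`): skeleton statistics are enhanced with
  `TFCE(v) = sum_h e(h, v)^E h^H dh` over `h = dh, 2dh, ...`, where
  `e(h, v)` is the extent of the connected component containing `v`
  at threshold `h` on the supplied adjacency. Defaults `E = 0.5`,
  `H = 2` and `dh = max(t)/100` follow the de-facto standard for this
  enhancement. The transform is computed in C++ with an incremental
  union-find over descending thresholds, so a 100-step enhancement of
  a skeleton costs O(steps × (voxels + edges)). Corrected p values per
  sign come from the max-TFCE permutation null.

Both analyses are run as two one-sided tests, mirroring how positive
and negative associations are reported separately; calibration checks
therefore measure the rejection rate per contrast.

## Spatially-aware annotation

Cross-region correlations between a statistic map and annotation maps
(neurotransmitter densities, behavioral-domain activations) are biased
if significance is judged against value-shuffling nulls, because smooth
maps have far fewer effective degrees of freedom than regions. The
package uses variogram-matched surrogates: a Gaussian random field with
exponential covariance `exp(-d / l)` is drawn over the region
centroids, and the observed values are reassigned in the field's rank
order. Every surrogate is thus an exact permutation of the observed
values that approximately preserves the empirical variogram; the length
scale `l` is fitted to the observed map's variogram by least squares
unless supplied. Rank remapping over centroids was chosen over
spherical rotation because the parcellation is volumetric, not a
surface. The test suite demonstrates that naive shuffling understates
the null spread on smooth maps (anti-conservative) relative to these
surrogates.

`assoc_test()` computes Pearson correlations of residuals after
regressing both maps on the regional gray-matter probability (partial
volume adjustment), a two-sided permutation p on |r|, and
Benjamini–Hochberg FDR within each family — neurotransmitter and
behavioral families are corrected separately, matching how the two
inventories are reported. The map inventories are data, not code:
any region × map table can be supplied, and the generator ships
synthetic stand-ins (27 neurotransmitter-like, 50 behavioral-like
maps).

## Transcriptomic association

The expression interface is a processed region × gene matrix; donor-
level probe selection and normalization are upstream concerns, though
`normalize_expression()` provides a per-gene scaled robust sigmoid for
synthetic matrices. Per-gene scores are Spearman correlations with the
phenotype map (robust to non-Gaussian expression; Pearson available).

**Ensemble GCEA.** A category's score is the mean member-gene score;
its null recomputes the scores against each surrogate phenotype while
keeping the real expression matrix, so both spatial autocorrelation and
gene–gene co-expression survive into the null. `p_ens` is the two-sided
(on |score|) rank with the >= tie convention, so a degenerate ensemble
equal to the phenotype yields p = 1 rather than the minimum — validity
under ties was preferred to rewarding degenerate ensembles. Categories
below `min_size` (default 5) are skipped with a message.

**PLS.** With a single response, the first partial least squares
component has weights proportional to the predictor–response
cross-covariance `X'y` (equivalently the first left singular vector of
the cross-covariance), against which the implementation is cross-
checked. Weights are sign-aligned so the component-score–phenotype
correlation `r` is non-negative; significance is the one-sided rank of
`r` against surrogate-phenotype refits. `select_top_loadings()`
interprets "top 25%" as a shared budget: `floor(0.25 * n_genes)` genes
ranked by |loading|, split by sign into PLS+ and PLS− — for a
5013-gene panel this yields 1253 selected genes split by sign, which is
the arithmetic that matches how such sets are reported (e.g. 698 + 555).

## Group and mediation statistics

`two_sample_t()` accepts raw vectors or printed group summaries
(means, SDs, ns) so published demographic tables can be recomputed
directly; pooled is the default, Welch available.
`chi_square_2x2()` is the Pearson statistic without continuity
correction. `partial_correlation()` correlates covariate residuals with
`df = n - 2 - k`; `roi_clinical_corr()` applies BH-FDR across all
(measure, clinical) pairs of a family — the family is defined per
measure-set × clinical-set, configurable by how the caller batches
pairs. `fisher_z_compare()` implements
`z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`.

`mediate()` fits the three OLS path models with covariates in every
equation (`m ~ x`, `y ~ x + m`, `y ~ x`), reports unstandardized
coefficients, and bootstraps the indirect effect `a*b` over subject
resamples with a percentile interval (default `n_boot = 5000`,
95% CI). The percentile interval — rather than bias-corrected — is the
current default of the standard macro for this analysis; the OLS
identity `c = c' + a*b` holds on any complete-case fit and is asserted
to 1e-10. Missing clinical values are handled by listwise deletion,
matching the per-analysis n variation typical of clinical tables. Sex
is encoded 0/1; categorical sensitivity covariates (antidepressant
type) enter one-hot.

## The synthetic cohort

`cohort_spec()` defaults encode the study conditions: 120 patients and
118 controls; CRP log-normal with log-scale location −0.513 and scale
0.993 — matching a patient mean near 0.98 mg/L with SD 1.27 — clamped
to the observed 0.02–6.39 mg/L range (the skew motivates the
log-normal); age 42.9 ± 11.0 vs 43.8 ± 13.9 years; education
8.9 ± 3.7 vs 11.6 ± 4.7 years; ~67% female in both groups; FD
0.13 ± 0.05 mm; BMI 23 ± 3.3 kg/m².

Planted effects (standardized): `beta_crp_falff = 0.6` on the
low-frequency amplitude inside a 3×3×3 seeded cluster (patients only),
`beta_crp_ad = -0.6` on a contiguous 30-voxel skeleton strip, and
mediation paths `a = 0.5`, `b = 0.5`, `c' = 0`, giving a population
indirect effect of 0.25. The effect sizes are free parameters — no
published correlation was available to calibrate them — set large
enough that a 120-subject cohort detects them reliably, which is what
a recovery test needs. Exact-correlation constructions are used
throughout (signal `beta·z + sqrt(1-beta^2)·e` against standardized
log CRP `z`), so the planted population correlation equals the stated
beta rather than merely approaching it.

The latent mediator is injected as the subject's planted-cluster
sinusoid amplitude, so extracted cluster fALFF genuinely mediates the
CRP–score association end to end. BOLD series are broadband Gaussian
noise plus a 0.05 Hz sinusoid with random voxel phase; the default grid
is 24×24×24 voxels (3 mm), 200 timepoints at TR 2 s, which resolves
0.01 Hz with two full cycles. Gene maps are Gaussian random fields with
exponential covariance (length scale 15 mm) over region centroids, so
they carry realistic spatial autocorrelation; planted-category genes
are noisy copies of a designated phenotype pattern; annotation maps are
smooth fields with a planted subset constructed to correlate with the
phenotype at a stated `r_target`. The synthetic atlas partitions the
mask into 60 compact regions (k-means on voxel coordinates) — a
desk-scale stand-in preserving the cross-region statistics of a
246-region design.

What the generator does **not** emulate: hemodynamics, scanner
artifacts, motion, registration error, anatomically realistic
parcellations, donor-level expression assembly, or correlated nuisance
structure between covariates and imaging. Passing recovery tests shows
the estimators are correct and calibrated under the stated generative
model, not that real acquisitions meet those assumptions.

## Numerical choices and degenerate inputs

* Permutation and ensemble p values use `(1 + #{null >= obs})/(n + 1)`
  throughout: never zero, conservative under ties.
* Constant series → fALFF 0 with a warning; maps fully explained by the
  adjustment covariate → partial correlation 0 rather than noise from
  ~0/0; zero-variance mediation variables and rank-deficient designs
  are errors naming the offending variable.
* All randomness flows through integer seeds; sub-stream seeds are
  derived by hashing (stage, subject) labels into 31-bit integers, so
  any subject's volume is reproducible in isolation and identical
  seeds give bit-identical outputs.
* Voxel indices are 1-based internally; world coordinates are voxel ×
  size (mm). NIfTI output uses double precision so round trips are
  bit-exact.
* `run_pipeline()` writes a JSON manifest with the configuration hash
  and per-output md5; stages whose configuration and outputs are
  unchanged are skipped and reloaded on re-run.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to keep the full suite in
a few minutes while leaving planted effects comfortably detectable:
cluster recovery on a 14^3 grid with 128 timepoints and 120 patients;
null calibration of both FWE procedures over 200 pure-noise cohorts of
40 subjects at 500 permutations each (rejection below 0.08 at
alpha = 0.05, per one-sided contrast); surrogate-p uniformity over
eight statistic maps × 50 independent smooth maps; ensemble GCEA with
25 categories and 500 surrogates; mediation recovery at n = 2000 and
percentile-CI coverage over 300 replicates at `n_boot = 1000`
(0.95 ± 0.03). The acceptance script repeats these measurements from
scratch at the same scales with the seed supplied on the command line.

## Known limitations

Cluster-level inference is permutation-based, not random-field theory,
so corrected p values are exchangeability-based and depend on the
permutation count. The surrogate generator matches the variogram of the
observed map through a single exponential length scale; maps with
strongly anisotropic or multi-scale autocorrelation will be matched
only approximately. GCEA p values are bounded below by
`1/(n_surr + 1)`, so category rankings saturate at the floor when many
surrogates would be needed to separate very strong signals. The
mediation model is a single-mediator OLS path model; multiple mediators
and moderated mediation are out of scope.
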