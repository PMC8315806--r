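---
title: "Mapping symptom geometry onto global brain connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping symptom geometry onto global brain connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbsmap)
```

## The problem

Psychosis spectrum disorders (schizophrenia, schizoaffective disorder,
bipolar disorder with psychosis) are diagnosed categorically, but their
symptoms and cognitive deficits vary continuously and cross-diagnostically.
`bbsmap` implements a pipeline for relating that variation to resting-state
functional connectivity summarized per brain region: it reduces a clinical
battery (canonically 30 psychosis-symptom items plus 6 cognitive scores) to
a few orthogonal symptom dimensions, maps each dimension onto parcellated
global brain connectivity (GBC), quantifies how stable and reproducible the
univariate and multivariate versions of that mapping are, selects the most
predictive parcels for single-subject indices, and benchmarks the resulting
maps against external reference maps (e.g. pharmacological contrasts).

Everything is exercised on synthetic cohorts with planted ground truth, so
each stage has a recoverable answer.

## Global brain connectivity

For parcel time series $x_p(t)$, GBC is the mean Fisher-z transformed
Pearson correlation of each parcel with all others:

$$\mathrm{GBC}(p) = \frac{1}{P-1} \sum_{q \neq p} \operatorname{atanh}(r_{pq}).$$

Two numerical points. First, a literal row mean of the correlation matrix
would include the self-correlation $r_{pp}=1$, whose Fisher z is infinite;
the only finite reading excludes the diagonal, which `compute_gbc()` does.
Second, the z-transform is applied *before* averaging, so GBC is in z
units and the estimator variance is approximately stabilized across
correlation magnitudes.

Frame censoring (`scrub_mask()`) flags frames with frame displacement above
0.5 mm or intensity RMS change above 1.6 times the scan median, discards
each flagged frame together with its two temporal neighbors (single pass —
a frame removed only as a neighbor does not spawn further removals), and
subjects with more than half their frames flagged should be excluded
(`scrub_exclusion()`). Censoring deletes columns; nothing is interpolated.

### Parcellate first, then correlate

The pipeline averages vertex series into parcels before computing
correlations. In simulation, when vertex noise is identically distributed
across subjects, computing dense GBC and then averaging the GBC values is
statistically comparable — vertex averaging of z values is itself an
efficient estimator. The ordering matters when vertex noise amplitude
varies across subjects (scanner and motion heterogeneity, which is the
realistic regime): dense correlations then attenuate subject-dependently,
injecting symptom-irrelevant between-subject GBC variance that
parcel-averaging before correlation removes. Our ordering test plants
exactly that structure and the parcellate-first pipeline yields
systematically larger association statistics (mean t-ratio about 1.4).

## Symptom dimensionality reduction

`fit_pca()` standardizes each item to unit variance and eigen-decomposes
the item correlation matrix. Signs are fixed by making the
largest-magnitude element of every loading column positive, so resampled
solutions are comparable; all cross-fit comparisons additionally match
components by greedy maximum absolute correlation.

Component significance (`permutation_significance()`) shuffles subject
order independently within every item, refits, and compares each observed
variance fraction against the null distribution of the *same component
rank* (the Horn-style reading of "variance exceeding chance"). P-values
use the add-one estimator, $(1+\#\{null \ge obs\})/(1+B)$, and
standardization is redone inside each permutation (a formality, since
shuffling preserves marginals). Held-out subjects are projected with the
training means, standard deviations and loadings (`project_scores()`);
controls can be projected without ever entering the fit.

## The synthetic cohort generator

`generate_cohort()` plants the study conditions the pipeline assumes:

* **Symptoms**: 36 items driven by 5 independent standard-normal latent
  factors through random orthogonal loading columns scaled so the factors
  carry 20%, 11%, 8%, 7% and 5% of total item variance (about half
  jointly, mirroring the low-rank clinical geometry the pipeline targets);
  Gaussian item noise fills the remainder, and items are standardized.
  An optional factor-correlation matrix makes the factors oblique.
* **Neural data**: 718 parcels per subject composed of a parcel baseline,
  a global per-subject offset (sd 0.2), three shared symptom-irrelevant
  components jointly carrying 45% of parcel variance (geometrically
  decreasing shares, echoing the observation that the first few neural
  components are common to patients and controls), factor-coupled
  coefficient maps confined to disjoint 100-parcel signal sets with
  coupling strength 0.5, and unit-scale parcel noise.
* **Labels**: six sites assigned round-robin at random (optional additive
  site intercepts, default zero, exist to exercise leave-site-out tests);
  diagnosis labels cut the first factor score at quantiles, giving
  overlapping groups — diagnosis never enters the neural generative model,
  it only stratifies resampling.

Effect sizes are not published for the symptom-neural couplings; the
defaults above were chosen once so that full-sample univariate maps are
clearly detectable at n = 436 while a 180-feature CCA is not — the
qualitative regime the pipeline is meant to expose. All draws flow from
per-block sub-streams of one master seed, so identical configurations are
bit-identical.

What the generator does *not* emulate: raw BOLD dynamics, spatial
autocorrelation of parcels, non-Gaussian item distributions, missing data,
scanner drift, or site effects beyond additive intercepts. Passing tests
therefore demonstrate correctness and calibration of the estimators under
a linear-Gaussian cohort model, not robustness to every pathology of real
clinical data.

## Mass-univariate mapping and family-wise error

`map_symptom_to_gbc()` regresses each parcel's GBC on one score (OLS with
intercept; optional covariates are residualized from both sides first) and
Z-scores the coefficient map across parcels so maps are comparable across
predictors. Family-wise error control uses the max-statistic permutation
test (`permutation_fwe()`): shuffle the predictor, record the maximum
|t| across parcels, and compare each observed |t| to that null. This
controls the family-wise error rate strongly at the parcel level while
preserving the spatial covariance of GBC; dense-resolution cluster
enhancement is intentionally out of scope.

Shared neural variance can be removed by fitting a PCA on GBC from
patients and controls combined (`fit_neural_pca()`) and reconstructing
patient data without the leading components
(`partial_out_neural_pcs()`); when the symptom-coupled variance is not
aligned with the removed components, the beta map survives nearly
unchanged — the planted-design test verifies correlation above 0.95 after
removing the dominant shared component.

## CCA, its instability, and the required sample size

`fit_cca()` Z-scores both feature sets and takes the SVD of the whitened
cross-covariance; variates have unit variance, within-set variates are
uncorrelated, and canonical correlations are non-increasing. Mode
significance permutes the symptom side (both within-set covariances are
untouched by construction) with rank-matched nulls and Benjamini-Hochberg
FDR across modes. Fitting requires more subjects than total features and
rank-deficient sets are rejected with advice to reduce features
(symmetrize parcels with `symmetrize_cortex()`, or use PC scores).

The package reproduces the central methodological contrast in silico: at
n = 436 with 180 neural features, 5 symptom features and a planted true
canonical correlation of 0.3, split-half neural loadings correlate below
0.5 on average while symptom-PCA loadings on cohorts of the same size
replicate above 0.8; leave-one-subject-out latent predictions collapse
toward zero while in-sample canonical correlations stay inflated
(`loo_latent_prediction()` exposes both).

`required_sample_size()` asks how many subjects a *stable* CCA would need.
It builds a joint covariance over standardized features encoding exactly
one canonical mode at the requested correlation (diagonal within-set
covariance; rank-one cross-covariance $\Sigma_{xy} = r\,\Sigma_{xx} w_x
w_y^\top \Sigma_{yy}$ with weights normalized to unit variate variance),
simulates replicates at candidate n, and bisects a geometric grid (factor
1.25) for the smallest n at which permutation power reaches 90% and four
error metrics fall to 10%: relative association error $|\hat r - r|/r$,
weight error $1-|\cos|$ (worse of the two sets), the analogous loading
error, and score error $1-|\mathrm{corr}|$. These formulas are this
package's declared definitions; the originals live in an external tool
whose internals are not reproduced here.

Two within-set spectra are available. The default identity spectrum gives
every feature equal variance; with 180-by-5 features at r = 0.3 the four
errors cross the 10% target between n = 8,000 and 16,000, i.e. a
five-figure sample — an order of magnitude beyond typical clinical
cohorts. A power-law spectrum ($\lambda_i \propto i^{-1}$) is provided as
an option, but with uniformly random weight vectors most of the planted
weight mass then sits in near-zero-variance directions, the weight and
score errors plateau around 0.2 regardless of n, and no finite sample
meets a 10% weight-error target; the headline sample-size computation
therefore uses the identity spectrum. The acceptance script runs this at
100 replicates and 50 permutations per grid point.

## dpGBC and step-down parcel selection

For patient selection the pipeline works with deviation maps
$\Delta\mathrm{GBC}$ (subject minus group mean, `delta_gbc()`; an external
reference mean is allowed for replication cohorts) and the dot-product
index `dpgbc()` — the sum over a parcel subset of the deviation times a
reference coefficient map. Unlike a correlation it is unbounded and
sign-carrying, and it is linear in the deviation map.

`loo_dpgbc_eval()` is strictly leakage-free: for each subject, both the
coefficient map and the group mean are recomputed from the other N−1
subjects, and the score-on-dpGBC regression applied to the held-out
subject is also fitted without them (rank-one downdates make this O(NP)).
Metric A is the correlation between observed dpGBC indices and the symptom
scores; metric B between observed and predicted indices. (Because the
predicted index is an affine function of the score, a literal
"predicted-vs-predicted" correlation would be identically 1; the two
metrics implemented are the ones that carry information, and they
necessarily peak together.)

`stepdown_select()` ranks parcels once by the full-sample |beta| (ties
broken by index) and eliminates from the weakest up, evaluating the
leave-one-out metrics at every retained count (for more than 200 parcels,
a decimated grid with exact refinement around the provisional peak;
re-ranking per step is not exposed because per-parcel OLS slopes do not
depend on the retained set, so re-ranking is a no-op). The selected subset
maximizes metric A; metric B's argmax is reported alongside.

A property worth knowing before interpreting selected subsets: because the
ranking uses the full sample, parcels that correlate with the score by
chance contribute a first-order *gain* to metric A even beyond the true
signal set. On planted cohorts (n = 436, 100 parcels, 20 signal) the curve
argmax therefore drifts to roughly 30–35 retained parcels and the
best-subset Jaccard overlap with the planted set sits near 0.6; on pure
null cohorts the maximum of the metric-A curve has median about 0.25
rather than zero. These are properties of the selection procedure itself
(verified against brute-force refits), and they temper how sharply a
selected parcel count should be read on real data.

## Benchmarking and patient selection

`map_similarity()` compares maps by Spearman (default, for the
rank-based similarity convention) or Pearson correlation, optionally on a
subset; maps in different parcel spaces must be symmetrized explicitly.
`pharma_contrast()` turns drug-vs-placebo GBC into a Z-scored t-contrast
reference map. `select_patients()` implements the two-stage rule: keep
subjects with |score| at or above a symptom threshold (both poles of a
bi-directional axis are symptomatic), then keep those whose deviation-map
similarity to the reference map is at least the neural threshold in
magnitude *and* matches the sign of their score. Default thresholds — the
75th percentile of |score| and 0.25 similarity — are user parameters, as
no canonical values exist. The rule is monotone: raising either threshold
never adds subjects. `generate_reference_map()` manufactures reference
maps at an exact target correlation by orthogonal-residual mixing, which
lets the benchmark tests sweep reference fidelity.

## Simulation sizes and numerical choices

The test suite runs everything at sizes a single CPU completes in minutes,
chosen as the package's own study conditions: cohorts of n = 436 (the
canonical discovery-sample size) for recovery, stability and selection
checks; type-I calibration at 200 null seeds with 500 permutations
(200 subjects × 10 items for the symptom PCA; 80 subjects × 718 parcels
for the max-statistic test; 100 subjects, 8-by-5 features for CCA modes);
100 split-half runs for the replication contrast; and 100 Monte-Carlo
replicates per grid point in the power analysis. Correlations at |r| = 1
are clamped away from the atanh pole at 1e-15; eigen-decompositions treat
eigenvalues below 1e-10 of the maximum as rank deficiency; permutation
p-values are never zero by construction; ties in |beta| break by parcel
index for determinism.

## Known limitations

* The cohort model is linear-Gaussian with additive site effects; it does
  not probe robustness to skewed item distributions, outliers, or
  correlated parcel noise.
* CIFTI/NIFTI binary imaging formats are out of scope; all interchange is
  labeled tab-delimited text.
* The power analysis's error-metric definitions are declared substitutes
  for an external tool's; absolute required-sample-size values should be
  read at order-of-magnitude resolution.
* Step-down selection inherits the selection optimism described above;
  split-sample validation of a selected subset is the honest follow-up.

## A minimal session

```{r, eval = FALSE}
cfg <- cohort_config(n_subjects = 200, n_parcels = 100, seed = 1)
cohort <- generate_cohort(cfg)
ps <- permutation_significance(cohort$symptoms, n_perm = 1000, seed = 2)
ps$n_significant
bm <- map_symptom_to_gbc(ps$solution$scores[, 1], cohort$gbc)
sel <- stepdown_select(cohort$gbc, ps$solution$scores[, 1])
ref <- generate_reference_map(bm$coefficients, 0.76, seed = 3)
map_similarity(bm$coefficients, ref, method = "spearman")
```

The same stages run end-to-end, with artifacts and provenance on disk,
through `run_pipeline(default_pipeline_config(seed = 1))`.
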