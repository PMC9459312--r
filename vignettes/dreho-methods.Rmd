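---
title: "Dynamic regional homogeneity: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic regional homogeneity: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dreho)
```

## The measure

Regional homogeneity (ReHo) quantifies how synchronously a voxel and its
immediate neighbours fluctuate during a resting-state fMRI scan. It is
Kendall's coefficient of concordance over the $K$ time series of a voxel
neighbourhood (here $K \le 27$, the voxel and its 26 face/edge/corner
neighbours), observed at $n$ time points:

$$W \;=\; \frac{12 \sum_{i=1}^{n} (R_i - \bar R)^2}
               {K^2 (n^3 - n) \; - \; K \sum_{j=1}^{K} T_j},$$

where $R_i$ is the sum across series of the rank of time point $i$, and
$T_j = \sum (t^3 - t)$ over the tie groups of series $j$. $W = 1$ when all
series share one rank ordering; for $K$ independent series $E[W] = 1/K$.
Because $W$ is a rank statistic it is invariant to any strictly monotone
transform of each series — a property the test suite exercises directly.

*Dynamic* ReHo asks how this local synchrony fluctuates over the scan: $W$
is recomputed inside a sliding window (default length 30 TR, step 1 TR, at
TR = 2 s) and each voxel is summarised by the across-window standard
deviation of its windowed $W$ series (coefficient of variation available
via `metric = "cv"`). A 30 TR window at TR 2 s spans 60 s, comfortably
above $1/f_{\min} = 1/0.01\,\mathrm{Hz} = 100$ s only for the upper part of
the pass band; window lengths of 25 and 35 TR are first-class
configuration values so the stability of results across window choices can
be checked (`pipeline_config(window_lengths = c(30, 25, 35))`).

Within-mask neighbourhoods shrink at mask edges rather than being
zero-padded: a boundary voxel's $W$ uses only its in-mask neighbours, with
$K$ recorded per voxel in the map's `extra$K`. The windowed computation is
implemented in C++; for the 27-voxel neighbourhood the cross-series rank
sums are separable 3×3×3 box sums of the per-voxel rank images, which
makes the per-window cost linear in voxels, and the compiled path is
checked bit-for-bit against the plain per-neighbour path and against a
pure-R brute force built on `kendall_w()`.

## Single-subject chain

`subject_dreho()` runs, in a fixed order:

1. **Volume discard** — the first 10 volumes are dropped (magnetisation
   equilibration), so a 240-volume acquisition analyses 230 volumes.
2. **Detrending** — per-voxel least-squares linear trend removal, keeping
   the temporal mean. Detrending a finite band-limited series is not a
   projection that commutes with the filter: re-running detrend+filter
   changes the result at the percent level, so only the filter itself is
   idempotent, and the pipeline applies the chain exactly once.
3. **Band-pass** — an ideal (brick-wall) frequency-domain filter keeps
   Fourier components with $0.01 \le f \le 0.08$ Hz and removes DC. The
   brick-wall choice is exactly testable on pure tones (in-band amplitude
   preserved to <1%, a 0.2 Hz tone attenuated >100-fold) and is linear,
   which the suite also verifies.
4. **dReHo mapping** as above.
5. **Normalisation** — division by the whole-brain (in-mask) mean
   (`"mean-div"`, default), z-scoring (`"zscore"`), both in sequence, or
   `"none"`. Mean-division and z-scoring are both offered because the two
   conventions coexist in the dynamic-ReHo literature and summaries of
   map amplitude are sometimes reported on either scale; the default is
   mean-division.
6. **Smoothing** — separable Gaussian, FWHM 6 mm
   ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, converted to voxels per axis),
   with kernel weights renormalised over the in-mask support so constants
   are preserved and nothing leaks across the mask edge. Smoothing comes
   last, after variability and normalisation.

Head motion is consumed, not estimated: six-parameter traces are screened
with the exclusion rule (any |translation| > 1.5 mm or any axis rotation
> 1.5° excludes the subject, each axis compared independently), and the
per-subject nuisance scalar is the mean framewise displacement — summed
absolute frame-to-frame differences of the six parameters with rotations
converted to millimetres of arc on a 50 mm sphere. A single scalar per
subject is what a between-subject GLM can absorb.

## Group inference

`group_inference()` fits, per voxel, an ordinary least squares model with
intercept, group indicator, and nuisance covariates (age, education years,
mean framewise displacement by default); the statistic is the group
coefficient over its standard error on $n - p$ degrees of freedom. With no
nuisance columns this reduces exactly to the pooled-variance two-sample t,
which the tests verify to $10^{-10}$.

Cluster correction follows Gaussian random field theory:

* **Smoothness** is estimated from the voxelwise-standardised GLM
  residuals via the lag-one spatial autocorrelation per axis under a
  Gaussian autocorrelation model,
  $\mathrm{FWHM}_k = \sqrt{2\ln 2 / (-\ln \hat\rho_k)}$ voxels (floored at
  0.5 voxel for stability), and the resel count is the mask volume over
  the FWHM product. On white noise smoothed with a known 6 mm kernel the
  estimator recovers the kernel width within 15%.
* **Extent threshold**: with $E[m]$ the expected suprathreshold cluster
  count from the 3D Euler-characteristic density and $E[N]$ the expected
  suprathreshold volume, cluster sizes follow
  $P(s \ge k) = \exp(-\beta k^{2/3})$ with
  $\beta = (\Gamma(5/2)\,E[m]/E[N])^{2/3}$, and the family-wise rate is
  $1 - \exp(-E[m] P(s \ge k))$; the smallest $k$ keeping this at or below
  the cluster-level $p$ is used.
* **Two-tailed** inference is run as two one-tailed analyses at half the
  voxel-level $p$ each (default: voxel $p < 0.01$ two-tailed, cluster
  $p < 0.05$ per tail). The t-map is thresholded at the exact t quantile;
  the random-field quantities use the Gaussian density by default since
  between-subject designs here have large degrees of freedom — a t-field
  Euler-characteristic option (`field = "t"`) is available, and the
  connectivity of cluster components (26 by default) is configurable
  because published pipelines rarely state it.

Surviving clusters are reported with size, peak t, 0-based peak voxel
index and world-mm peak coordinates through the affine, ordered by |peak
t|. Per-subject cluster means feed the association and classification
stages. The chain's empirical family-wise error, measured over 500
simulated null cohorts (16³ voxels, 20+20 subjects, 6 mm smoothing) by
`fwe_calibration()`, sits near the nominal 0.05 — the acceptance suite
requires [0.02, 0.10].

## Association and classification

Demographics tables use Welch's unequal-variance t from the raw values;
recomputing the statistic from published group summaries with
`welch_ttest_from_summary()` reproduces printed table t-values only under
the Welch form, which is why the pooled form is not offered. The Pearson
screen between cluster means and clinical variables (patients only) is
uncorrected by default, with a Benjamini–Hochberg option. Scoring rules:
MoCA gains one point below 12 years of education, capped at 30; AHI bands
are <5 / 5–<15 / 15–<30 / >30 with 30 itself assigned to the severe band
(the conventional strict inequalities leave it uncovered); ESS bands are
strict at >6, >11, >16.

Classification is a leave-one-out cross-validated soft-margin linear SVM
(cost 1) on cluster-mean features, patients positive. Features are
standardised with training-fold statistics only, so adding constants or
rescaling features cannot change any metric. The SVM solver is libsvm's
hinge-loss formulation via e1071; on standardised one- or few-dimensional
cluster-mean features at default cost its decision rule is effectively
identical to a squared-hinge linear classifier. Using group-defined
clusters as LOOCV features inherits the circularity of the published
design; this is deliberate (it is the procedure being reproduced) and the
reported numbers should be read as descriptive of that procedure, not as
unbiased out-of-sample accuracy. A fully nested variant,
`nested_loocv_svm()`, re-runs the entire group inference inside every
training fold and predicts the held-out subject from that fold's own
clusters — slower, fold-dependent in its feature space, but free of the
selection circularity.

## The synthetic cohort generator

No patient data are available, so every stage is validated on simulated
two-group studies (`cohort_spec()`, `simulate_cohort()`):

* **Clinical tables** draw each variable as an independent truncated
  Gaussian per group, with reference means/SDs matching a published
  moderate-to-severe OSA cohort (79 patients, 84 controls) and hard scale
  bounds (MoCA 0–30, ESS 0–24, percentages 0–100). A zero SD degenerates
  to the mean, which is allowed and tested.
* **Scans** are independent band-limited Gaussian noise per voxel (plus an
  intensity offset and a small linear drift that preprocessing removes).
  Inside each spherical effect region all voxels share a common
  band-limited signal mixed in with weight
  $w(t) = \mathrm{mix}\,(1 + d\,e(t))$, where $e(t)$ is a sinusoidal or
  boxcar envelope and the modulation depth $d$ is `base_depth` for
  controls and `base_depth + sign × amplitude` for patients (clipped to
  [0, 0.95]), scaled by a per-subject multiplier. Deeper modulation makes
  the windowed $W$ of the region swing more, so the across-window SD —
  the dReHo signal — separates the groups with the injected sign, and
  `ground_truth_effect` records the depth difference map.
* **Motion traces** are smoothed random walks kept strictly inside the
  1.5 mm / 1.5° bounds, or scaled to violate them on demand so the
  screening rule can be exercised from both sides.
* **Coupling**: covariates named in `coupling` are re-drawn, within the
  patient group, against each subject's *measured* injected-region dReHo
  (computed on the ground-truth sphere during simulation) with noise set
  so the target correlation holds in expectation. Calibrating against the
  measured rather than the injected quantity means the Pearson stage can
  be tested without attenuation from measurement noise.

Everything is a pure function of the spec and its seed: per-subject
streams are derived by hashing the seed with the subject id and a purpose
tag, so regenerating any piece is bit-identical and independent of
generation order.

What the generator does **not** emulate: anatomy, physiological noise,
scanner drift beyond a linear term, spatial autocorrelation of the
baseline noise (the background is white before smoothing), or motion
artefacts in the voxel data (traces are metadata). Passing recovery tests
therefore demonstrate that the pipeline's statistics behave as designed on
signals with known ground truth — not that the effect sizes or accuracies
correspond to any clinical population. Injected modulation depths are free
parameters of the simulation, not calibrated to OSA.

## Desk-scale validation experiments

Two Monte-Carlo experiments validate the full chain at sizes a single CPU
handles comfortably; the sizes are design choices of the package's own
validation studies and are stated here once.

**Null calibration** (`fwe_calibration()`): 500 cohorts of 20+20 smoothed
white-noise maps on a 16³ grid; any surviving cluster in either tail is a
family-wise false positive. This checks the smoothness estimator, the
extent threshold and the component labelling jointly.

**Effect recovery** (`effect_recovery_study()`): 20 seeded cohorts per
injected amplitude (0.1, 0.25, 0.4) of 12+12 subjects on a 14×14×12 grid
of 3 mm voxels, 160 volumes at TR 2 s, one positive radius-3 sphere,
boxcar envelope with period 64 TR and fixed phase, between-subject depth
multiplier SD 0.08, window 30 TR at step 2. The design was frozen after a
power pilot: with random envelope phases and a sinusoidal envelope the
between-subject variance of the region summary is dominated by
realisation noise rather than the injected depth, leaving desk-scale
group inference underpowered; phase-locking the boxcar envelope removes
that variance component while leaving the measured quantity unchanged.
Recovery requires exactly one surviving cluster overlapping the sphere
with the injected sign. LOOCV accuracy on the region-mean feature must be
non-decreasing in the injected amplitude.

One normalisation caveat discovered in piloting and worth stating
generally: dividing by the whole-brain mean presumes the effect occupies a
negligible brain fraction. On a desk-scale grid the injected sphere is
~3% of the mask and carries values well above baseline, so mean-division
transfers part of the group difference into the background with opposite
sign, which then survives correction as spurious negative clusters. The
recovery experiment therefore runs with `norm = "none"`; on whole-brain
data (where clusters are ~0.1–0.5% of the mask) the bias is negligible
and the default remains mean-division.

## Numerical conventions

* Voxel indices are 0-based in all file outputs; windows are half-open
  `[start, end)` in TR units; world coordinates are mm through the affine.
* Degenerate inputs: neighbourhoods with fewer than 2 in-mask members get
  $W = 0$; constant series are mid-ranked and absorbed by the tie
  correction; an all-constant window yields $W = 0$ rather than 0/0;
  constant classifier features are dropped with a warning; zero in-mask
  mean or variance makes normalisation/z-scoring an error rather than a
  silent NaN map.
* Smoothness FWHMs are floored at 0.5 voxel; the GRF extent threshold is
  at least 1 voxel.
* All tables are tibbles; `tidy()`/`glance()` methods cover the classifier
  objects; NIfTI-1 (plain or gzipped) is the image format throughout, with
  the TR stored in `pixdim[4]`.
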