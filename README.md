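# dreho

Dynamic regional homogeneity mapping and group inference for resting-state
fMRI, with a seeded synthetic-cohort generator so the whole analysis chain
can be validated end to end without patient data.

## What it does, and for whom

Regional homogeneity (ReHo) measures the local synchrony of spontaneous
brain activity: Kendall's coefficient of concordance *W* among the time
series of a voxel and its neighbours,

    W = 12 * S / ( K^2 (n^3 - n) - K * sum(T_j) ),

where `S` is the spread of cross-series rank sums over the `n` time
points, `K` the neighbourhood size (27 by default) and `T_j` the usual tie
corrections. *Dynamic* ReHo (dReHo) recomputes `W` in a sliding window
(30 TR length, 1 TR step at TR = 2 s by default) and maps each voxel's
across-window standard deviation — a voxelwise index of how much local
coherence fluctuates during the scan. It was proposed for studying
disorders such as obstructive sleep apnoea, where patients and controls
differ in the temporal variability of local activity.

The package implements the full study pipeline a clinical resting-state
group comparison needs:

* temporal preprocessing: volume discard, per-voxel detrending, ideal
  0.01–0.08 Hz band-pass, head-motion screening (1.5 mm / 1.5°) with mean
  framewise displacement as the nuisance scalar;
* static ReHo and sliding-window dReHo maps (compiled core), global-mean /
  z-score normalisation, mask-aware Gaussian smoothing (6 mm FWHM);
* voxelwise covariate-adjusted two-sample inference with Gaussian random
  field cluster correction (voxel p < .01 two-tailed, cluster p < .05) and
  cluster tables with peak coordinates;
* clinical association: Welch t demographics tables, Pearson screens of
  cluster means against clinical scores, MoCA/AHI/ESS scoring rules;
* leave-one-out cross-validated linear-SVM classification on cluster-mean
  features with accuracy/precision/sensitivity/specificity and ROC/AUC;
* a two-group synthetic cohort generator (clinical tables with realistic
  covariate structure, 4D scans with injected group-dependent coherence
  dynamics, motion traces) driving Monte-Carlo validation of every stage.

Tables are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_map_slice()` graphics; images are NIfTI-1.

## Worked example

Simulate a desk-scale study (12 patients + 12 controls, 14x14x12 grid of
3 mm voxels, 160 volumes at TR 2 s) with one injected coherence-modulated
sphere, and run the full pipeline:

```r
library(dreho)

spec   <- desk_study_spec(amplitude = 0.4, seed = 7)
cohort <- simulate_cohort(spec)
run <- run_pipeline(
  cohort,
  pipeline_config(window_lengths = 30L, window_step = 2L, norm = "none",
                  seed = 7L),
  out_dir = "dreho_run"
)
run
#> <pipeline_run> 24/24 subjects retained, 1 window length(s)
#>   window_30TR: 1 cluster(s), LOOCV accuracy 91.7%

run$windows$window_30TR$inference$clusters$table
#> # A tibble: 1 × 10
#>   cluster  sign n_voxels peak_t peak_i peak_j peak_k peak_x_mm peak_y_mm
#>     <int> <dbl>    <int>  <dbl>  <int>  <int>  <int>     <dbl>     <dbl>
#> 1       1     1      233   6.65      9      6      6        27        18

glance(run$windows$window_30TR$svm)
#> # A tibble: 1 × 6
#>   accuracy precision sensitivity specificity   auc     n
#>      <dbl>     <dbl>       <dbl>       <dbl> <dbl> <int>
#> 1     91.7      91.7        91.7        91.7 0.993    24
```

The injected positive sphere is recovered as a single GRF-surviving
cluster (233 voxels, peak t = 6.65 at the sphere's location), all 24
subjects pass motion screening, and the cluster-mean feature classifies
patients from controls at 91.7% LOOCV accuracy with AUC 0.993. The run
directory holds the manifest, demographics table, t-map and cluster-label
NIfTIs, cluster/correlation/ROC tables and JSON sidecars stamped with the
configuration hash.

Summary-level association works without any imaging at all — recomputing a
published demographics row from its printed summaries:

```r
welch_ttest_from_summary(54.0, 21.7, 79, 2.2, 1.2, 84)
#> # A tibble: 1 × 3
#>       t   dof        p
#>   <dbl> <dbl>    <dbl>
#> 1  21.2  78.4 3.39e-34
```

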