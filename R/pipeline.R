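#' Analysis pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. The default
#' window length is 30 TR with a 1 TR step; supplying several lengths (for
#' instance `c(30, 25, 35)`) runs the mapping, inference and downstream
#' stages once per length, the first being the primary analysis.
#'
#' @param prep A [prep_config()].
#' @param window_lengths Integer vector of window lengths (TR).
#' @param window_step Window step (TR, default 1).
#' @param connectivity ReHo neighbourhood size: 7, 19 or 27.
#' @param metric `"sd"` or `"cv"` across-window variability.
#' @param norm `"mean-div"`, `"zscore"` or `"both"` map normalisation.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param voxel_p,cluster_p Inference thresholds (two-tailed voxel p and
#'   per-tail cluster-level FWE).
#' @param cluster_connectivity Component connectivity for clusters.
#' @param field `"gaussian"` or `"t"` random-field model.
#' @param covariates Nuisance covariates for the group design.
#' @param correlate_with Clinical variables screened against cluster means.
#' @param svm_cost Soft-margin cost for the classifier.
#' @param seed Seed recorded in the run log.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(prep = prep_config(),
                            window_lengths = 30L, window_step = 1L,
                            connectivity = 27L,
                            metric = c("sd", "cv"),
                            norm = c("mean-div", "zscore", "both", "none"),
                            fwhm_mm = 6,
                            voxel_p = 0.01, cluster_p = 0.05,
                            cluster_connectivity = 26L,
                            field = c("gaussian", "t"),
                            covariates = c("age", "education",
                                           "motion_summary"),
                            correlate_with = c("ahi", "odi", "nadir_sao2",
                                               "sleep_period_time",
                                               "moca_total", "ess"),
                            svm_cost = 1, seed = 1L) {
  structure(
    list(prep = prep, window_lengths = as.integer(window_lengths),
         window_step = as.integer(window_step),
         connectivity = as.integer(connectivity),
         metric = match.arg(metric), norm = match.arg(norm),
         fwhm_mm = fwhm_mm, voxel_p = voxel_p, cluster_p = cluster_p,
         cluster_connectivity = as.integer(cluster_connectivity),
         field = match.arg(field), covariates = covariates,
         correlate_with = correlate_with, svm_cost = svm_cost,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Normalise a dReHo map according to the configured convention
#'
#' @param map A [scalar_map()].
#' @param norm `"mean-div"`, `"zscore"`, `"both"` (mean-division followed
#'   by z-scoring) or `"none"`. Global rescaling assumes effects occupy a
#'   negligible fraction of the brain; `"none"` is appropriate when they do
#'   not (see the methods vignette).
#' @return A [scalar_map()].
#' @export
normalize_map <- function(map, norm = c("mean-div", "zscore", "both",
                                        "none")) {
  norm <- match.arg(norm)
  switch(norm,
    "mean-div" = normalize_by_global_mean(map),
    "zscore" = zscore_map(map),
    "both" = zscore_map(normalize_by_global_mean(map)),
    "none" = map
  )
}

#' Per-subject dReHo map through the full single-subject chain
#'
#' Preprocess (discard, detrend, band-pass), compute the sliding-window
#' concordance variability map, normalise, smooth.
#'
#' @param vol Raw [volume4d()].
#' @param config A [pipeline_config()].
#' @param length_tr Window length to use (defaults to the first configured).
#' @return A [scalar_map()].
#' @export
subject_dreho <- function(vol, config = pipeline_config(),
                          length_tr = config$window_lengths[1]) {
  pv <- prep_volume(vol, config$prep)
  m <- dreho_map(pv, connectivity = config$connectivity,
                 length_tr = length_tr, step_tr = config$window_step,
                 metric = config$metric)
  m <- normalize_map(m, config$norm)
  gaussian_smooth(m, config$fwhm_mm)
}

#' Motion screening of a whole cohort
#'
#' @param cohort A `simulated_cohort` (or any list with `clinical` and
#'   `motion` fields).
#' @param prep A [prep_config()].
#' @return Manifest tibble: `subject_id`, `group`, `retained`,
#'   `motion_summary`, `max_translation_mm`, `max_rotation_deg`, `reason`.
#' @export
screen_cohort <- function(cohort, prep = prep_config()) {
  purrr::map2_dfr(cohort$motion, names(cohort$motion), function(tr, id) {
    s <- motion_screen(tr, prep)
    grp <- cohort$clinical$group[cohort$clinical$subject_id == id]
    tibble::tibble(subject_id = id, group = grp, retained = s$retained,
                   motion_summary = s$motion_summary,
                   max_translation_mm = s$max_translation_mm,
                   max_rotation_deg = s$max_rotation_deg,
                   reason = s$reason)
  })
}

# Dice overlap between the cluster label maps of two analyses.
cluster_overlap <- function(a, b) {
  A <- a$labels > 0
  B <- b$labels > 0
  denom <- sum(A) + sum(B)
  if (denom == 0) return(NA_real_)
  2 * sum(A & B) / denom
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages, in order: head-motion screening; per-subject preprocessing and
#' dReHo mapping (per configured window length); demographics comparison;
#' covariate-adjusted group inference with GRF cluster correction;
#' cluster-mean extraction; Pearson screening against clinical variables
#' (patients only); leave-one-out linear-SVM classification. All tables,
#' statistic images, cluster label images and JSON sidecars are written
#' under `out_dir`; rerunning with an identical cohort and configuration
#' reproduces the outputs exactly.
#'
#' @param cohort A `simulated_cohort` with scans.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_run`: `manifest`, `demographics`,
#'   and per-window-length results (`inference`, `features`,
#'   `correlations`, `svm`), plus `window_overlap` when several lengths are
#'   configured and `out_dir`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = tempfile("dreho_run_")) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(cohort$scans)) stop("cohort has no scans", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("dreho pipeline run  [config %s]",
                         config_hash(config)),
                 sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", R.version.string))

  manifest <- screen_cohort(cohort, config$prep)
  for (i in which(!manifest$retained)) {
    log_lines <- c(log_lines, sprintf("excluded %s: %s",
                                      manifest$subject_id[i],
                                      manifest$reason[i]))
  }
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  kept <- manifest$subject_id[manifest$retained]
  if (length(unique(manifest$group[manifest$retained])) < 2L) {
    stop("fewer than two groups retained after motion screening",
         call. = FALSE)
  }
  clinical <- dplyr::inner_join(
    cohort$clinical,
    manifest[, c("subject_id", "motion_summary")],
    by = "subject_id"
  )
  clinical <- clinical[clinical$subject_id %in% kept, ]
  demo <- demographics_table(clinical)
  readr::write_tsv(demo, file.path(out_dir, "demographics.tsv"))

  per_window <- list()
  for (wl in config$window_lengths) {
    wdir <- file.path(out_dir, sprintf("window_%02dTR", wl))
    dir.create(wdir, showWarnings = FALSE)
    maps <- purrr::map(cohort$scans[kept], function(s) {
      subject_dreho(s$volume, config, length_tr = wl)
    })
    design <- build_design(clinical, config$covariates)
    inf <- group_inference(maps, design, voxel_p = config$voxel_p,
                           cluster_p = config$cluster_p,
                           connectivity = config$cluster_connectivity,
                           field = config$field)
    tmap <- scalar_map(inf$stat$t, mask = inf$stat$mask,
                       affine = inf$stat$affine, label = "tstat")
    write_volume(tmap, file.path(wdir, "tstat.nii.gz"))
    write_volume(inf$clusters$labels * 1L,
                 file.path(wdir, "cluster_labels.nii.gz"))
    readr::write_tsv(inf$clusters$table,
                     file.path(wdir, "clusters.tsv"))
    write_sidecar(
      list(config_hash = config_hash(config), window_length_tr = wl,
           window_step_tr = config$window_step,
           connectivity = config$connectivity, metric = config$metric,
           norm = config$norm, fwhm_mm = config$fwhm_mm,
           voxel_p = config$voxel_p, cluster_p = config$cluster_p,
           field = config$field, dof = inf$stat$dof,
           fwhm_vox = inf$stat$fwhm, resels = inf$stat$resels,
           extent_k = inf$k, seed = config$seed),
      file.path(wdir, "inference.json")
    )
    res <- list(inference = inf, features = NULL, correlations = NULL,
                svm = NULL)
    if (nrow(inf$clusters$table) > 0) {
      feats <- cluster_means(maps, inf$clusters, subject_ids = kept)
      readr::write_tsv(feats, file.path(wdir, "cluster_means.tsv"))
      cors <- correlate_clusters(feats, clinical, config$correlate_with)
      readr::write_tsv(cors, file.path(wdir, "correlations.tsv"))
      labels <- clinical$group[match(feats$subject_id,
                                     clinical$subject_id)]
      svm <- loocv_linear_svm(feats, labels, C = config$svm_cost)
      readr::write_tsv(tidy(svm), file.path(wdir, "svm_folds.tsv"))
      readr::write_tsv(tidy(svm$roc), file.path(wdir, "roc.tsv"))
      write_sidecar(as.list(glance(svm)),
                    file.path(wdir, "svm_report.json"))
      res$features <- feats
      res$correlations <- cors
      res$svm <- svm
    } else {
      log_lines <- c(log_lines,
                     sprintf("window %d TR: no surviving clusters", wl))
    }
    per_window[[sprintf("window_%02dTR", wl)]] <- res
    log_lines <- c(log_lines,
                   sprintf("window %d TR: %d cluster(s), extent k = %d",
                           wl, nrow(inf$clusters$table), inf$k))
  }

  overlap <- NULL
  if (length(config$window_lengths) > 1L) {
    wl <- config$window_lengths
    pairs <- utils::combn(seq_along(wl), 2)
    overlap <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- per_window[[pairs[1, j]]]$inference$clusters
      b <- per_window[[pairs[2, j]]]$inference$clusters
      tibble::tibble(window_a = wl[pairs[1, j]], window_b = wl[pairs[2, j]],
                     dice = cluster_overlap(a, b))
    })
    readr::write_tsv(overlap, file.path(out_dir, "window_overlap.tsv"))
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  structure(
    list(manifest = manifest, demographics = demo, windows = per_window,
         window_overlap = overlap, config = config, out_dir = out_dir),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d/%d subjects retained, %d window length(s)\n",
              sum(x$manifest$retained), nrow(x$manifest),
              length(x$windows)))
  for (nm in names(x$windows)) {
    inf <- x$windows[[nm]]$inference
    cat(sprintf("  %s: %d cluster(s)", nm, nrow(inf$clusters$table)))
    if (!is.null(x$windows[[nm]]$svm)) {
      cat(sprintf(", LOOCV accuracy %.1f%%",
                  x$windows[[nm]]$svm$metrics$accuracy))
    }
    cat("\n")
  }
  invisible(x)
}
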