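#' Build a group + nuisance design matrix
#'
#' Columns: intercept, group indicator (patient = 1, control = 0), then the
#' requested nuisance covariates taken from the clinical table.
#'
#' @param clinical Tibble with a `group` column (`"patient"`/`"control"`)
#'   and one column per covariate.
#' @param covariates Character vector of nuisance covariate names (default
#'   `c("age", "education", "motion_summary")`).
#' @return Numeric matrix with attribute `contrast` (the group column index).
#' @export
build_design <- function(clinical,
                         covariates = c("age", "education",
                                        "motion_summary")) {
  stopifnot("group" %in% names(clinical))
  grp <- as.numeric(clinical$group == "patient")
  if (length(unique(grp)) < 2L) {
    stop("both groups must be present", call. = FALSE)
  }
  X <- cbind(intercept = 1, group = grp)
  for (cv in covariates) {
    if (!cv %in% names(clinical)) {
      stop("covariate not found in clinical table: ", cv, call. = FALSE)
    }
    X <- cbind(X, stats::setNames(list(as.numeric(clinical[[cv]])), cv)[[1]])
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient",
                                 call. = FALSE)
  attr(X, "contrast") <- 2L
  X
}

map_stack <- function(maps) {
  stopifnot(length(maps) >= 2L)
  m1 <- maps[[1]]
  stopifnot(inherits(m1, "scalar_map"))
  for (m in maps[-1]) {
    if (!identical(dim(m$data), dim(m1$data)) ||
        !identical(m$mask, m1$mask)) {
      stop("all maps must share grid and mask", call. = FALSE)
    }
  }
  idx <- which(m1$mask)
  Y <- vapply(maps, function(m) m$data[idx], numeric(length(idx)))
  list(Y = t(Y), idx = idx, mask = m1$mask, affine = m1$affine)
}

#' Voxelwise covariate-adjusted two-sample t-map
#'
#' Ordinary least squares fit of each voxel's values on the design; the
#' statistic is the group coefficient divided by its standard error, with
#' `n - rank(X)` degrees of freedom. With no nuisance columns this is
#' exactly the pooled-variance two-sample t-test at every voxel.
#'
#' @param maps List of per-subject [scalar_map()]s sharing grid and mask.
#' @param design Design matrix from [build_design()] (rows match `maps`).
#' @return Object of class `stat_map`: `t` (3D array), `dof`, `mask`,
#'   `affine`, `residuals` (subjects x in-mask voxels, for smoothness
#'   estimation), `idx` (in-mask linear indices).
#' @export
voxelwise_glm_ttest <- function(maps, design) {
  st <- map_stack(maps)
  X <- as.matrix(design)
  n <- nrow(X)
  if (n != length(maps)) stop("design rows must match number of maps",
                              call. = FALSE)
  p <- ncol(X)
  ci <- attr(design, "contrast")
  if (is.null(ci)) ci <- 2L
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, st$Y)
  resid <- st$Y - X %*% beta
  dof <- n - p
  sigma2 <- colSums(resid^2) / dof
  se <- sqrt(XtXinv[ci, ci] * sigma2)
  tval <- beta[ci, ] / se
  tarr <- array(0, dim = dim(st$mask))
  tarr[st$idx] <- tval
  structure(
    list(t = tarr, dof = dof, mask = st$mask, affine = st$affine,
         residuals = resid, idx = st$idx),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> dof %d, t range [%.3f, %.3f], %d in-mask voxels\n",
              x$dof, min(x$t[x$idx]), max(x$t[x$idx]), length(x$idx)))
  if (!is.null(x$fwhm)) {
    cat(sprintf("  smoothness FWHM (vox): %s; resels %.1f\n",
                paste(sprintf("%.2f", x$fwhm), collapse = ", "), x$resels))
  }
  invisible(x)
}

#' Estimate map smoothness from GLM residuals
#'
#' Per-axis FWHM (in voxels) of the residual fields, from the
#' lag-one spatial autocorrelation of the voxelwise-standardised residuals
#' under a Gaussian autocorrelation model:
#' `FWHM = sqrt(2 log 2 / (-log rho))`. The resel count is the in-mask
#' volume divided by the product of the per-axis FWHMs.
#'
#' @param residuals Subjects x in-mask-voxels residual matrix (e.g. from
#'   [voxelwise_glm_ttest()]).
#' @param mask Logical 3D array; `ncol(residuals)` must equal `sum(mask)`.
#' @return List: `fwhm` (length 3, voxels), `resels`.
#' @export
estimate_smoothness <- function(residuals, mask) {
  stopifnot(nrow(residuals) >= 2L, ncol(residuals) == sum(mask))
  d <- dim(mask)
  norm <- sqrt(colSums(residuals^2))
  if (any(norm == 0)) stop("constant (all-zero) residuals at some voxel",
                           call. = FALSE)
  U <- sweep(residuals, 2L, norm, `/`)
  idx <- which(mask)
  vox_id <- array(0L, dim = d)
  vox_id[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    nxt <- ijk
    nxt[, ax] <- nxt[, ax] + 1L
    ok <- nxt[, ax] <= d[ax]
    j <- rep(0L, nrow(nxt))
    j[ok] <- vox_id[nxt[ok, , drop = FALSE]]
    has <- j > 0L
    if (!any(has)) { fwhm[ax] <- 0.5; next }
    a <- which(has)
    lam <- mean(colSums((U[, j[a], drop = FALSE] -
                           U[, a, drop = FALSE])^2))
    rho <- min(max(1 - lam / 2, 1e-6), 1 - 1e-6)
    fwhm[ax] <- max(sqrt(2 * log(2) / (-log(rho))), 0.5)
  }
  list(fwhm = fwhm, resels = sum(mask) / prod(fwhm))
}

#' Attach estimated smoothness to a stat map
#'
#' @param stat A `stat_map` from [voxelwise_glm_ttest()].
#' @return The `stat_map` with `fwhm` and `resels` fields filled.
#' @export
add_smoothness <- function(stat) {
  stopifnot(inherits(stat, "stat_map"))
  s <- estimate_smoothness(stat$residuals, stat$mask)
  stat$fwhm <- s$fwhm
  stat$resels <- s$resels
  stat
}

# Expected-cluster-count (EC density) and expected suprathreshold volume for
# a 3D field thresholded at u, over `resels` resolution elements and
# `n_voxels` voxels.
grf_expected <- function(u, resels, n_voxels, dof = Inf,
                         field = c("gaussian", "t")) {
  field <- match.arg(field)
  if (field == "gaussian" || !is.finite(dof)) {
    rho3 <- (4 * log(2))^1.5 / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
    p_vox <- stats::pnorm(u, lower.tail = FALSE)
  } else {
    rho3 <- (4 * log(2))^1.5 / (2 * pi)^2 *
      (1 + u^2 / dof)^(-(dof - 1) / 2) * ((dof - 1) / dof * u^2 - 1)
    p_vox <- stats::pt(u, dof, lower.tail = FALSE)
  }
  list(Em = max(resels * rho3, 1e-12), EN = n_voxels * p_vox)
}

#' Gaussian-random-field cluster extent threshold
#'
#' Smallest cluster size k (voxels) such that the family-wise probability of
#' observing any suprathreshold cluster of at least k voxels is at most
#' `cluster_p`, using the standard expected-cluster-count and
#' cluster-size-tail approximation
#' `P(n >= k) = exp(-beta k^(2/3))`,
#' `FWE(k) = 1 - exp(-E[m] P(n >= k))`.
#' Two-tailed inference is handled by the caller as two one-tailed analyses
#' at `voxel_p / 2` each, with `cluster_p` per tail.
#'
#' @param stat A `stat_map` with smoothness attached ([add_smoothness()]).
#' @param voxel_p_tail One-tailed voxel probability threshold (e.g. 0.005
#'   for a two-tailed 0.01 analysis).
#' @param cluster_p Cluster-level family-wise error target per tail
#'   (default 0.05).
#' @param field Treat the statistic field as `"gaussian"` (default; the
#'   degrees of freedom of a between-subject fMRI design are large) or use
#'   the t-field Euler-characteristic density (`"t"`).
#' @return Extent threshold k (integer, voxels).
#' @export
grf_cluster_extent_threshold <- function(stat, voxel_p_tail = 0.005,
                                         cluster_p = 0.05,
                                         field = c("gaussian", "t")) {
  field <- match.arg(field)
  stopifnot(inherits(stat, "stat_map"), !is.null(stat$resels))
  u <- if (field == "gaussian") {
    stats::qnorm(voxel_p_tail, lower.tail = FALSE)
  } else {
    stats::qt(voxel_p_tail, stat$dof, lower.tail = FALSE)
  }
  ex <- grf_expected(u, stat$resels, length(stat$idx), stat$dof, field)
  if (ex$EN <= 0) stop("expected suprathreshold volume is zero", call. = FALSE)
  nbar <- ex$EN / ex$Em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  target <- -log(1 - cluster_p)
  if (ex$Em <= target) return(1L)
  k <- (log(ex$Em / target) / beta)^(3 / 2)
  max(1L, as.integer(ceiling(k)))
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the t-map at the one-tailed t quantile per sign, labels
#' connected components under the chosen connectivity, keeps components of
#' at least `k` voxels, and reports each surviving cluster's size, peak t,
#' and peak coordinates (0-based voxel indices and world mm via the
#' affine). Clusters are ordered by decreasing |peak t|, ties broken by
#' voxel coordinates.
#'
#' @param stat A `stat_map`.
#' @param k Extent threshold in voxels (may be a single value or
#'   `c(pos, neg)`).
#' @param voxel_p_tail One-tailed voxel probability (default 0.005).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Object of class `cluster_set`: `table` (tibble with columns
#'   `cluster`, `sign`, `n_voxels`, `peak_t`, `peak_i/j/k`, `peak_x/y/z_mm`)
#'   and `labels` (3D integer array, 0 = background).
#' @export
extract_clusters <- function(stat, k, voxel_p_tail = 0.005,
                             connectivity = 26L) {
  stopifnot(inherits(stat, "stat_map"), connectivity %in% c(6L, 18L, 26L))
  if (length(k) == 1L) k <- c(k, k)
  tcrit <- stats::qt(voxel_p_tail, stat$dof, lower.tail = FALSE)
  d <- dim(stat$mask)
  rows <- list()
  labels <- array(0L, dim = d)
  next_label <- 0L
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, dim = d)
    supra[stat$idx] <- sgn * stat$t[stat$idx] > tcrit
    if (!any(supra)) next
    lab <- cpp_label_components(as.logical(supra), as.integer(d),
                                as.integer(connectivity))
    kmin <- if (sgn > 0) k[1] else k[2]
    sizes <- tabulate(lab[lab > 0L])
    for (comp in which(sizes >= kmin)) {
      vox <- which(lab == comp)
      tv <- stat$t[vox]
      peak <- vox[which.max(abs(tv))]
      pijk <- arrayInd(peak, d) - 1L  # 0-based
      world <- voxel_to_world(pijk, stat$affine)
      next_label <- next_label + 1L
      labels[vox] <- next_label
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sign = sgn, n_voxels = length(vox),
        peak_t = tv[which.max(abs(tv))],
        peak_i = pijk[1], peak_j = pijk[2], peak_k = pijk[3],
        peak_x_mm = world[1], peak_y_mm = world[2], peak_z_mm = world[3],
        .label = next_label
      )
    }
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(sign = numeric(), n_voxels = integer(),
                   peak_t = numeric(), peak_i = integer(),
                   peak_j = integer(), peak_k = integer(),
                   peak_x_mm = numeric(), peak_y_mm = numeric(),
                   peak_z_mm = numeric(), .label = integer())
  }
  if (nrow(tab) > 0) {
    ord <- order(-abs(tab$peak_t), tab$peak_i, tab$peak_j, tab$peak_k)
    tab <- tab[ord, ]
    relab <- array(0L, dim = d)
    for (i in seq_len(nrow(tab))) {
      relab[labels == tab$.label[i]] <- i
    }
    labels <- relab
    tab$cluster <- seq_len(nrow(tab))
  } else {
    tab$cluster <- integer()
  }
  tab <- dplyr::select(tab, "cluster", "sign", "n_voxels", "peak_t",
                       dplyr::starts_with("peak_"))
  structure(list(table = tab, labels = labels), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d surviving cluster(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Full covariate-adjusted group inference on a stack of maps
#'
#' Convenience chain: GLM t-map, residual smoothness, per-tail GRF extent
#' threshold at `voxel_p / tails`, cluster extraction.
#'
#' @inheritParams voxelwise_glm_ttest
#' @param voxel_p Two-tailed voxel threshold (default 0.01).
#' @param cluster_p Cluster-level FWE target per tail (default 0.05).
#' @param connectivity Component connectivity (default 26).
#' @param field `"gaussian"` or `"t"` random-field model.
#' @return List of class `group_inference`: `stat` (stat_map with
#'   smoothness), `k` (extent threshold), `clusters` (`cluster_set`),
#'   `voxel_p`, `cluster_p`, `connectivity`, `field`.
#' @export
group_inference <- function(maps, design, voxel_p = 0.01, cluster_p = 0.05,
                            connectivity = 26L,
                            field = c("gaussian", "t")) {
  field <- match.arg(field)
  stat <- add_smoothness(voxelwise_glm_ttest(maps, design))
  k <- grf_cluster_extent_threshold(stat, voxel_p_tail = voxel_p / 2,
                                    cluster_p = cluster_p, field = field)
  cl <- extract_clusters(stat, k, voxel_p_tail = voxel_p / 2,
                         connectivity = connectivity)
  structure(
    list(stat = stat, k = k, clusters = cl, voxel_p = voxel_p,
         cluster_p = cluster_p, connectivity = connectivity, field = field),
    class = "group_inference"
  )
}

#' @export
print.group_inference <- function(x, ...) {
  print(x$stat)
  cat(sprintf("  voxel p %.3g (two-tailed), cluster p %.3g, extent k = %d\n",
              x$voxel_p, x$cluster_p, x$k))
  print(x$clusters)
  invisible(x)
}

#' Per-subject cluster-mean values
#'
#' Averages each subject's map over every surviving cluster; these are the
#' features fed to the correlation and classification stages.
#'
#' @param maps List of per-subject [scalar_map()]s.
#' @param clusters A `cluster_set` from [extract_clusters()].
#' @param subject_ids Optional character vector of ids (defaults to
#'   `names(maps)` or `subj<i>`).
#' @return Tibble: `subject_id` plus one `cluster<i>` column per cluster.
#' @export
cluster_means <- function(maps, clusters, subject_ids = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (nrow(clusters$table) == 0L) {
    stop("no clusters to average over", call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- names(maps)
    if (is.null(subject_ids)) {
      subject_ids <- sprintf("subj%03d", seq_along(maps))
    }
  }
  out <- tibble::tibble(subject_id = subject_ids)
  for (ci in clusters$table$cluster) {
    vox <- which(clusters$labels == ci)
    if (any(!maps[[1]]$mask[vox])) {
      stop("cluster ", ci, " extends outside the map mask", call. = FALSE)
    }
    out[[paste0("cluster", ci)]] <-
      vapply(maps, function(m) mean(m$data[vox]), numeric(1))
  }
  out
}
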