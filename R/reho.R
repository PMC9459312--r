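#' Kendall's coefficient of concordance
#'
#' Rank-based agreement among K time series observed at the same n time
#' points — the statistic behind regional homogeneity (ReHo). With
#' cross-series rank sums \eqn{R_i} and tie-correction terms
#' \eqn{T_j = \sum (t^3 - t)} per series,
#' \deqn{W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (n^3 - n) - K \sum_j T_j}.}
#' W is 1 exactly when all series share one rank ordering; under independence
#' its expectation is 1/K. Constant series are ranked with mid-ranks (all
#' equal), which is what the tie correction accounts for.
#'
#' @param series n x K numeric matrix: one column per series, one row per
#'   time point.
#' @return Concordance value in `[0, 1]` (0 only in fully degenerate cases).
#' @examples
#' x <- cbind(1:4, 1:4, 4:1)
#' kendall_w(x)  # 1/9
#' @export
kendall_w <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  K <- ncol(series)
  if (K < 2L) stop("need at least two series", call. = FALSE)
  if (n < 2L) stop("need at least two time points", call. = FALSE)
  rk <- apply(series, 2L, rank, ties.method = "average")
  ties <- vapply(seq_len(K), function(j) {
    t <- table(series[, j])
    sum(t^3 - t)
  }, numeric(1))
  Ri <- rowSums(rk)
  S <- sum((Ri - mean(Ri))^2)
  denom <- K^2 * (n^3 - n) - K * sum(ties)
  if (denom <= 0) return(0)
  12 * S / denom
}

#' Sliding-window schedule
#'
#' Half-open windows `[i*step, i*step + length)` over a series of
#' `n_timepoints`; the last window must fit entirely, so the count is
#' `floor((n - length)/step) + 1`.
#'
#' @param n_timepoints Number of time points available.
#' @param length_tr Window length in TR units (default 30).
#' @param step_tr Step between window starts in TR (default 1).
#' @return Tibble with columns `window`, `start`, `end` (0-based, half-open).
#' @examples
#' nrow(sliding_windows(230, 30, 1))  # 201
#' @export
sliding_windows <- function(n_timepoints, length_tr = 30L, step_tr = 1L) {
  n_timepoints <- as.integer(n_timepoints)
  length_tr <- as.integer(length_tr)
  step_tr <- as.integer(step_tr)
  if (length_tr < 2L) stop("window length must be >= 2", call. = FALSE)
  if (step_tr < 1L || step_tr > length_tr) {
    stop("step must satisfy 1 <= step <= length", call. = FALSE)
  }
  if (length_tr > n_timepoints) {
    stop("window length exceeds series length", call. = FALSE)
  }
  starts <- seq.int(0L, n_timepoints - length_tr, by = step_tr)
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    end = starts + length_tr
  )
}

nbhd_offsets <- function(connectivity = 27L) {
  if (!connectivity %in% c(7L, 19L, 27L)) {
    stop("connectivity must be one of 7, 19, 27", call. = FALSE)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "7" = m <= 1, "19" = m <= 2, "27" = m <= 3
  )
  g[keep, , drop = FALSE]
}

# Neighbour list for the in-mask voxels of `mask`, 1-based indices into the
# vector of in-mask voxels (column-major order). Out-of-mask neighbours are
# dropped, so K shrinks at mask edges.
mask_neighbours <- function(mask, connectivity = 27L) {
  d <- dim(mask)
  off <- nbhd_offsets(connectivity)
  idx <- which(mask)
  vox_id <- array(0L, dim = d)
  vox_id[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  nbr <- vector("list", length(idx))
  for (v in seq_along(idx)) {
    p <- sweep(off, 2L, ijk[v, ], `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] &
      p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    p <- p[ok, , drop = FALSE]
    ids <- vox_id[cbind(p[, 1], p[, 2], p[, 3])]
    nbr[[v]] <- ids[ids > 0L]
  }
  list(index = idx, neighbours = nbr, n_neighbours = lengths(nbr))
}

windowed_reho_values <- function(vol, connectivity, starts0, length_tr) {
  if (!any(vol$mask)) stop("mask is empty", call. = FALSE)
  Tn <- dim(vol$data)[4]
  if (connectivity == 27L) {
    res <- cpp_dreho27(as.numeric(vol$data), as.integer(dim(vol$data)),
                       as.logical(vol$mask), as.integer(starts0 + 1L),
                       as.integer(length_tr))
    idx <- which(vol$mask)
    return(list(values = res$w[idx, , drop = FALSE],
                nb = list(index = idx, n_neighbours = res$K[idx])))
  }
  nb <- mask_neighbours(vol$mask, connectivity)
  ts <- matrix(vol$data, ncol = Tn)[nb$index, , drop = FALSE]
  w <- cpp_windowed_reho(ts, nb$neighbours, as.integer(starts0 + 1L),
                         as.integer(length_tr))
  list(values = w, nb = nb)
}

#' Static regional homogeneity map
#'
#' Kendall's W of each in-mask voxel's neighbourhood time series over the
#' full scan. Boundary voxels use only their in-mask neighbours (K reduced
#' accordingly); the per-voxel neighbour count is stored in the map's
#' `extra$K`.
#'
#' @param vol A [volume4d()], already preprocessed.
#' @param connectivity Neighbourhood size including the centre: 7, 19 or 27
#'   voxels (default 27).
#' @return A [scalar_map()] labelled `"reho"`.
#' @export
reho_map <- function(vol, connectivity = 27L) {
  stopifnot(inherits(vol, "volume4d"))
  Tn <- dim(vol$data)[4]
  res <- windowed_reho_values(vol, connectivity, 0L, Tn)
  out <- array(0, dim = dim(vol$mask))
  out[res$nb$index] <- res$values[, 1]
  Kmap <- array(0L, dim = dim(vol$mask))
  Kmap[res$nb$index] <- res$nb$n_neighbours
  scalar_map(out, mask = vol$mask, affine = vol$affine, label = "reho",
             extra = list(K = Kmap))
}

#' Dynamic regional homogeneity (sliding-window variability) map
#'
#' Computes the windowed ReHo series of every in-mask voxel and summarises
#' its across-window variability: the standard deviation (`metric = "sd"`,
#' the default) or the coefficient of variation (`metric = "cv"`, sd/mean).
#'
#' @inheritParams reho_map
#' @param length_tr,step_tr Sliding-window length and step, in TR units.
#' @param metric `"sd"` or `"cv"`.
#' @return A [scalar_map()] labelled `"dreho_sd"` or `"dreho_cv"`, with the
#'   per-voxel neighbour count in `extra$K` and the window schedule in
#'   `extra$windows`.
#' @export
dreho_map <- function(vol, connectivity = 27L, length_tr = 30L, step_tr = 1L,
                      metric = c("sd", "cv")) {
  stopifnot(inherits(vol, "volume4d"))
  metric <- match.arg(metric)
  Tn <- dim(vol$data)[4]
  win <- sliding_windows(Tn, length_tr, step_tr)
  if (nrow(win) < 2L) {
    stop("need at least two windows to measure variability", call. = FALSE)
  }
  res <- windowed_reho_values(vol, connectivity, win$start, length_tr)
  sds <- apply(res$values, 1L, stats::sd)
  vals <- if (metric == "cv") {
    mu <- rowMeans(res$values)
    ifelse(mu > 0, sds / mu, 0)
  } else {
    sds
  }
  out <- array(0, dim = dim(vol$mask))
  out[res$nb$index] <- vals
  Kmap <- array(0L, dim = dim(vol$mask))
  Kmap[res$nb$index] <- res$nb$n_neighbours
  scalar_map(out, mask = vol$mask, affine = vol$affine,
             label = paste0("dreho_", metric),
             extra = list(K = Kmap, windows = win))
}

#' Normalise a map by its whole-brain (in-mask) mean
#'
#' Every in-mask voxel is divided by the in-mask mean, so the returned map
#' has in-mask mean exactly 1.
#'
#' @param map A [scalar_map()].
#' @return A [scalar_map()] labelled `"normalized"`.
#' @export
normalize_by_global_mean <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- mask_values(map)
  mu <- mean(v)
  if (abs(mu) < 1e-12) {
    stop("in-mask mean is (numerically) zero; cannot normalise", call. = FALSE)
  }
  out <- map$data / mu
  out[!map$mask] <- NA_real_
  scalar_map(out, mask = map$mask, affine = map$affine, label = "normalized",
             extra = map$extra)
}

#' Z-score a map over the mask
#'
#' Centres and scales the in-mask values to mean 0, sd 1.
#'
#' @param map A [scalar_map()].
#' @return A [scalar_map()] labelled `"zscored"`.
#' @export
zscore_map <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- mask_values(map)
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop("in-mask standard deviation is zero; cannot z-score", call. = FALSE)
  }
  out <- (map$data - mean(v)) / s
  out[!map$mask] <- NA_real_
  scalar_map(out, mask = map$mask, affine = map$affine, label = "zscored",
             extra = map$extra)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable 3D convolution (zero padding at the grid edge) via banded-matrix
# products along each axis.
smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    if (length(k) == 1L) next
    L <- d[ax]
    r <- (length(k) - 1L) / 2L
    B <- matrix(0, L, L)
    for (i in seq_len(L)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= L
      B[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- B %*% matrix(a, nrow = L)
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian smoothing of a scalar map
#'
#' Separable Gaussian convolution with kernel standard deviation
#' `fwhm / (2 sqrt(2 log 2))` mm per axis, converted to voxels using the
#' affine's voxel sizes. Kernel weights are renormalised over the in-mask
#' support, so a constant map passes through unchanged and no intensity
#' leaks across the mask edge.
#'
#' @param map A [scalar_map()].
#' @param fwhm_mm Full width at half maximum in mm (default 6); 0 is the
#'   identity.
#' @return A [scalar_map()] labelled `"smoothed"`.
#' @export
gaussian_smooth <- function(map, fwhm_mm = 6) {
  stopifnot(inherits(map, "scalar_map"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(map)
  vs <- voxel_sizes(map$affine)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  dat <- map$data
  dat[!map$mask] <- 0
  num <- smooth_3d(dat, sigma_vox)
  den <- smooth_3d(array(as.numeric(map$mask), dim = dim(map$mask)), sigma_vox)
  out <- array(NA_real_, dim = dim(dat))
  out[map$mask] <- num[map$mask] / den[map$mask]
  scalar_map(out, mask = map$mask, affine = map$affine, label = "smoothed",
             extra = map$extra)
}
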