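#' 4D volume container
#'
#' Wraps a 4D intensity array (x, y, z, t) together with the pieces of
#' metadata the pipeline needs: a voxel-to-world affine, the repetition time,
#' and a 3D logical brain mask. All spatial operations in the package respect
#' the mask; voxels outside it are never read or written.
#'
#' @param data Numeric 4D array, dimensions x, y, z, t.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param mask Logical 3D array matching the spatial dimensions of `data`.
#'   Defaults to all-`TRUE`.
#' @param affine 4x4 voxel-to-world transform (mm). Defaults to a diagonal
#'   affine built from `voxel_size_mm`.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm, used when `affine`
#'   is not supplied.
#'
#' @return An object of class `volume4d`: a list with elements `data`,
#'   `affine`, `tr_seconds`, `mask`.
#' @export
volume4d <- function(data, tr_seconds, mask = NULL, affine = NULL,
                     voxel_size_mm = c(3, 3, 3)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  }
  sdim <- dim(data)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dim = sdim)
  }
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!identical(dim(mask), as.integer(sdim))) {
    stop("mask shape must equal the spatial shape of `data`", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = sdim)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (is.null(affine)) {
    stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(
    list(data = data, affine = affine, tr_seconds = as.numeric(tr_seconds),
         mask = mask),
    class = "volume4d"
  )
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume4d> %d x %d x %d voxels, %d volumes, TR %.3g s, %d in-mask voxels\n",
    d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)
  ))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

#' 3D scalar map container
#'
#' A single 3D statistic or summary image (ReHo, dReHo variability, t-map,
#' ...) with its affine and mask. Values outside the mask are `NA`.
#'
#' @param data Numeric 3D array.
#' @param mask Logical 3D array, same shape; defaults to all voxels.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param label Character tag describing what the map holds, e.g. `"reho"`,
#'   `"dreho_sd"`, `"dreho_cv"`, `"normalized"`, `"smoothed"`.
#' @param extra Optional named list of auxiliary per-map data (for instance
#'   the per-voxel neighbour count `K` recorded by [reho_map()]).
#'
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, mask = NULL, affine = NULL, label = "map",
                       extra = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data))
  stopifnot(identical(dim(mask), dim(data)))
  mask <- array(as.logical(mask), dim = dim(data))
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  dat <- data
  dat[!mask] <- NA_real_
  if (any(!is.finite(dat[mask]))) {
    stop("scalar_map values must be finite inside the mask", call. = FALSE)
  }
  structure(
    list(data = dat, affine = affine, mask = mask, label = label,
         extra = extra),
    class = "scalar_map"
  )
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[x$mask]
  cat(sprintf(
    "<scalar_map:%s> %d x %d x %d, %d in-mask voxels, range [%.4g, %.4g]\n",
    x$label, d[1], d[2], d[3], sum(x$mask), min(v), max(v)
  ))
  invisible(x)
}

#' @export
dim.scalar_map <- function(x) dim(x$data)

#' In-mask values of a scalar map
#'
#' @param map A [scalar_map()].
#' @return Numeric vector of the values inside the mask (column-major order).
#' @export
mask_values <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  map$data[map$mask]
}

#' Voxel edge lengths implied by an affine
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return Length-3 numeric vector of voxel sizes in mm.
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Voxel indices to world (mm) coordinates
#'
#' Voxel indices are 0-based, matching the convention used in all file
#' outputs of this package.
#'
#' @param ijk Integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, affine) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}
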