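#' Read a 4D NIfTI volume
#'
#' Accepts plain or gzipped NIfTI-1 files. The repetition time is taken
#' from the file's 4th pixdim unless overridden.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mask Optional logical 3D array or path to a mask NIfTI.
#' @param tr_seconds Override the TR stored in the header.
#' @return A [volume4d()].
#' @export
read_volume <- function(path, mask = NULL, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D image, got ", length(dim(arr)), "D", call. = FALSE)
  }
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.null(tr_seconds)) {
    pd <- attr(img, "pixdim")
    tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  volume4d(arr, tr_seconds = tr_seconds, mask = mask,
           affine = unclass(RNifti::xform(img)))
}

#' Read a 3D NIfTI image as a mask
#'
#' @param path NIfTI file; non-zero voxels become TRUE.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("mask must be 3D", call. = FALSE)
  arr != 0
}

#' Read a 3D NIfTI image as a scalar map
#'
#' @param path NIfTI file.
#' @param mask Optional logical array or mask path.
#' @param label Map label.
#' @return A [scalar_map()].
#' @export
read_map <- function(path, mask = NULL, label = "map") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D image", call. = FALSE)
  if (is.character(mask)) mask <- read_mask(mask)
  scalar_map(arr, mask = mask, affine = unclass(RNifti::xform(img)),
             label = label)
}

#' Write a volume, map or mask as NIfTI-1
#'
#' Scalar-map voxels outside the mask are written as 0. The affine is
#' stored in both the sform and qform; for 4D volumes the TR goes into the
#' 4th pixdim.
#'
#' @param x A [volume4d()], [scalar_map()], or logical/numeric array.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "volume4d")) {
    arr <- x$data
    affine <- x$affine
    tr <- x$tr_seconds
  } else if (inherits(x, "scalar_map")) {
    arr <- x$data
    arr[!x$mask] <- 0
    affine <- x$affine
    tr <- NULL
  } else {
    arr <- x * 1
    affine <- diag(c(3, 3, 3, 1))
    tr <- NULL
  }
  img <- RNifti::asNifti(arr)
  # pixdim must be in place before the xforms so scales survive the write
  pd <- c(voxel_sizes(affine), if (is.null(tr)) 1 else tr)
  RNifti::pixdim(img) <- pd[seq_len(min(length(dim(arr)), 4L))]
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a motion trace as 6-column text
#'
#' Whitespace-delimited, no header: translations x, y, z in mm, then
#' rotations in degrees — the layout of realignment-parameter files.
#'
#' @param trace n x 6 matrix.
#' @param path Output text file.
#' @return `path` (write) or the n x 6 matrix (read).
#' @export
write_motion_trace <- function(trace, path) {
  m <- as_motion_matrix(trace)
  utils::write.table(format(m, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  m <- as_motion_matrix(m)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Write / read a clinical table as TSV
#'
#' One header row, tab separated.
#'
#' @param clinical Tibble.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

# Tiny rolling hash of a serialised object, used to stamp output sidecars so
# every file is traceable to the configuration that produced it.
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)),
             collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_sidecar <- function(info, path) {
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a cohort specification as a structured text file (JSON)
#'
#' @param spec A [cohort_spec()].
#' @param path JSON path.
#' @return `path` (write) or a [cohort_spec()] (read).
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  # JSON has no Inf literal; keep the bounds as strings and re-coerce on read
  x$covariate_params$lower <- as.character(x$covariate_params$lower)
  x$covariate_params$upper <- as.character(x$covariate_params$upper)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON encodes Inf bounds as strings; coerce numeric columns back
  renum <- function(df, keep = character()) {
    df <- tibble::as_tibble(df)
    for (cn in setdiff(names(df), keep)) df[[cn]] <- as.numeric(df[[cn]])
    df
  }
  cohort_spec(
    n_patients = x$n_patients, n_controls = x$n_controls,
    grid_shape = x$grid_shape, voxel_size_mm = x$voxel_size_mm,
    n_volumes = x$n_volumes, tr_seconds = x$tr_seconds,
    effect_regions = renum(x$effect_regions),
    covariate_params = renum(x$covariate_params, keep = "variable"),
    coupling = if (length(x$coupling)) {
      renum(x$coupling, keep = "variable")
    } else {
      NULL
    },
    base_depth = x$base_depth, base_mix = x$base_mix,
    envelope = x$envelope, envelope_phase = x$envelope_phase,
    envelope_period_tr = x$envelope_period_tr,
    subject_effect_sd = x$subject_effect_sd,
    analysis_window_length = x$analysis_window_length,
    analysis_window_step = x$analysis_window_step, seed = x$seed
  )
}
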