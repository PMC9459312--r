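#' Temporal preprocessing configuration
#'
#' Bundles the per-subject preprocessing parameters: how many initial
#' volumes to drop (magnetisation-equilibration scrub), the band-pass edges,
#' and the head-motion exclusion bounds.
#'
#' @param n_discard Initial volumes to drop (default 10).
#' @param band_low_hz,band_high_hz Pass-band edges in Hz (defaults 0.01 and
#'   0.08).
#' @param max_translation_mm Exclusion bound on any translation (default 1.5).
#' @param max_rotation_deg Exclusion bound on any rotation (default 1.5).
#' @param detrend Remove the per-voxel linear trend before filtering
#'   (default TRUE).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(n_discard = 10L, band_low_hz = 0.01,
                        band_high_hz = 0.08, max_translation_mm = 1.5,
                        max_rotation_deg = 1.5, detrend = TRUE) {
  stopifnot(n_discard >= 0, band_low_hz >= 0, band_high_hz > band_low_hz,
            max_translation_mm > 0, max_rotation_deg > 0)
  structure(
    list(n_discard = as.integer(n_discard), band_low_hz = band_low_hz,
         band_high_hz = band_high_hz, max_translation_mm = max_translation_mm,
         max_rotation_deg = max_rotation_deg, detrend = isTRUE(detrend)),
    class = "prep_config"
  )
}

#' Drop the initial volumes of a 4D series
#'
#' The first scans of an EPI acquisition are discarded to let magnetisation
#' reach steady state; a 240-volume series with the default 10 discarded
#' leaves 230 volumes.
#'
#' @param vol A [volume4d()].
#' @param n_discard Number of leading volumes to drop.
#' @return A shorter [volume4d()]; temporal order is preserved.
#' @export
discard_initial_volumes <- function(vol, n_discard = 10L) {
  stopifnot(inherits(vol, "volume4d"), n_discard >= 0)
  Tn <- dim(vol$data)[4]
  if (Tn <= n_discard) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, Tn),
         call. = FALSE)
  }
  if (n_discard == 0L) return(vol)
  volume4d(vol$data[, , , (n_discard + 1L):Tn, drop = FALSE],
           tr_seconds = vol$tr_seconds, mask = vol$mask, affine = vol$affine)
}

as_motion_matrix <- function(trace) {
  m <- as.matrix(trace)
  if (ncol(m) != 6L) {
    stop("a motion trace must have exactly 6 columns ",
         "(3 translations mm, 3 rotations deg)", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Mean framewise displacement of a motion trace
#'
#' Power-style scalar head-motion summary: per frame, the sum of absolute
#' frame-to-frame differences of the six rigid-body parameters, with the
#' three rotations converted from degrees to mm of arc on a 50 mm sphere;
#' the summary is the mean over frames.
#'
#' @param trace Matrix or data frame with 6 columns: translations x, y, z in
#'   mm then rotations in degrees.
#' @param radius_mm Sphere radius for the rotation-to-mm conversion.
#' @return Mean framewise displacement in mm (0 for a motionless trace).
#' @export
framewise_displacement <- function(trace, radius_mm = 50) {
  m <- as_motion_matrix(trace)
  if (nrow(m) < 2L) return(0)
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * pi / 180 * radius_mm
  mean(rowSums(d))
}

#' Head-motion screening
#'
#' A subject is excluded when any translation exceeds the bound in absolute
#' value on any axis, or any rotation angle does on any axis. The returned
#' row also carries the scalar motion summary (mean framewise displacement)
#' used downstream as a nuisance covariate.
#'
#' @param trace 6-column motion trace (translations mm, rotations degrees).
#' @param config A [prep_config()] holding the bounds.
#' @return One-row tibble: `retained`, `max_translation_mm`,
#'   `max_rotation_deg`, `motion_summary` (mean FD, mm), `reason` (`NA` when
#'   retained).
#' @export
motion_screen <- function(trace, config = prep_config()) {
  m <- as_motion_matrix(trace)
  if (nrow(m) == 0L) stop("motion trace is empty", call. = FALSE)
  max_t <- max(abs(m[, 1:3]))
  max_r <- max(abs(m[, 4:6]))
  bad_t <- max_t > config$max_translation_mm
  bad_r <- max_r > config$max_rotation_deg
  reason <- if (bad_t) {
    sprintf("translation %.3f mm > %.2f mm", max_t, config$max_translation_mm)
  } else if (bad_r) {
    sprintf("rotation %.3f deg > %.2f deg", max_r, config$max_rotation_deg)
  } else {
    NA_character_
  }
  tibble::tibble(
    retained = !(bad_t || bad_r),
    max_translation_mm = max_t,
    max_rotation_deg = max_r,
    motion_summary = framewise_displacement(m),
    reason = reason
  )
}

#' Remove the per-voxel linear trend
#'
#' Least-squares linear detrending of every voxel time series; the voxel
#' temporal mean is retained so intensities stay on their original scale.
#'
#' @param vol A [volume4d()] with at least 3 time points.
#' @return A [volume4d()] of the same shape.
#' @export
detrend_volume <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  Tn <- d[4]
  if (Tn < 3L) stop("need at least 3 time points to detrend", call. = FALSE)
  Y <- t(matrix(vol$data, ncol = Tn))      # T x V
  tt <- seq_len(Tn) - (Tn + 1) / 2         # centred regressor
  beta <- crossprod(tt, Y) / sum(tt^2)     # 1 x V slopes
  Y <- Y - tt %*% beta
  volume4d(array(t(Y), dim = d), tr_seconds = vol$tr_seconds,
           mask = vol$mask, affine = vol$affine)
}

#' Ideal band-pass filter of a 4D series
#'
#' Frequency-domain brick-wall filter: each voxel series is Fourier
#' transformed, components with frequency strictly outside
#' `[band_low_hz, band_high_hz]` are zeroed (the DC component always is),
#' and the series is inverse transformed. With TR 2 s the Nyquist frequency
#' is 0.25 Hz; the band must stay strictly below it.
#'
#' @param vol A [volume4d()].
#' @param config A [prep_config()] holding the band edges.
#' @return A filtered [volume4d()].
#' @export
bandpass_filter <- function(vol, config = prep_config()) {
  stopifnot(inherits(vol, "volume4d"))
  nyq <- 1 / (2 * vol$tr_seconds)
  if (config$band_high_hz >= nyq) {
    stop(sprintf("band_high (%.3g Hz) must be below Nyquist (%.3g Hz)",
                 config$band_high_hz, nyq), call. = FALSE)
  }
  d <- dim(vol$data)
  Tn <- d[4]
  Y <- t(matrix(vol$data, ncol = Tn))  # T x V
  f <- seq_len(Tn) - 1L
  f <- pmin(f, Tn - f) / (Tn * vol$tr_seconds)  # two-sided bin frequencies
  keep <- f >= config$band_low_hz & f <= config$band_high_hz & f > 0
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0+0i
  Y <- Re(stats::mvfft(Yf, inverse = TRUE)) / Tn
  volume4d(array(t(Y), dim = d), tr_seconds = vol$tr_seconds,
           mask = vol$mask, affine = vol$affine)
}

#' Full temporal preprocessing chain
#'
#' Applies, in order: initial-volume discard, per-voxel linear detrending
#' (optional), and ideal band-pass filtering. This is the fixed order used
#' throughout the pipeline; motion screening is a separate decision made
#' from the motion trace via [motion_screen()].
#'
#' @param vol A [volume4d()].
#' @param config A [prep_config()].
#' @return The preprocessed [volume4d()].
#' @export
prep_volume <- function(vol, config = prep_config()) {
  out <- discard_initial_volumes(vol, config$n_discard)
  if (config$detrend) out <- detrend_volume(out)
  bandpass_filter(out, config)
}
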