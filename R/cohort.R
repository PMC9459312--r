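# Seeded RNG helpers: every generator is a pure function of (spec, seed).
# Derived seeds are a rolling hash of the base seed and string keys, kept
# inside the 32-bit integer range R requires.

MOD31 <- 2147483647

derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% MOD31
  for (key in unlist(list(...))) {
    for (b in utf8ToInt(as.character(key))) {
      h <- (h * 131 + b) %% MOD31
    }
  }
  as.integer(h)
}

with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reference clinical covariate parameters
#'
#' Per-variable generating parameters for the two groups of a synthetic
#' obstructive-sleep-apnoea study: demographic, polysomnographic (AHI,
#' oxygen-saturation metrics, ODI, sleep times), cognitive (MoCA total and
#' its seven subscores) and sleepiness (ESS) variables, with the scale
#' bounds used for truncation. Defaults reproduce the group summary
#' statistics of a moderate-to-severe OSA cohort (n = 79) against healthy
#' controls (n = 84).
#'
#' @return Tibble with columns `variable`, `patient_mean`, `patient_sd`,
#'   `control_mean`, `control_sd`, `lower`, `upper`.
#' @export
table1_params <- function() {
  tibble::tribble(
    ~variable,            ~patient_mean, ~patient_sd, ~control_mean, ~control_sd, ~lower, ~upper,
    "age",                        38.5,         9.3,          45.3,        12.1,     18,     60,
    "education",                  12.8,         3.0,          11.2,         3.1,      0,    Inf,
    "bmi",                        27.2,         3.5,          21.1,         1.7,     10,     60,
    "total_sleep_time",          387.5,        98.4,         407.3,        22.9,      0,    Inf,
    "sleep_period_time",         460.9,        71.6,         441.8,        22.3,      0,    Inf,
    "sleep_efficiency",           83.6,        17.8,          92.2,         3.5,      0,    100,
    "ahi",                        54.0,        21.7,           2.2,         1.2,      0,    Inf,
    "sao2_below_90",              41.2,        48.1,          0.63,         1.3,      0,    100,
    "nadir_sao2",                 68.1,        12.4,          93.8,         3.6,      0,    100,
    "mean_sao2",                  92.0,         4.1,          96.9,         2.1,      0,    100,
    "odi",                        49.9,        24.6,           1.8,         1.1,      0,    Inf,
    "moca_total",                 24.4,         3.3,          28.0,         1.4,      0,     30,
    "moca_visuospatial",           3.9,         0.9,           4.7,         0.5,      0,      5,
    "moca_naming",                 2.9,         0.3,           2.9,         0.2,      0,      3,
    "moca_delayed_memory",         2.6,         1.5,           4.3,         0.6,      0,      5,
    "moca_attention",              5.1,         1.3,           5.5,         0.5,      0,      6,
    "moca_language",               2.2,         0.8,           2.7,         0.4,      0,      3,
    "moca_abstraction",            1.5,         0.5,           1.9,         0.2,      0,      2,
    "moca_orientation",            5.7,         0.7,           5.9,         0.3,      0,      6,
    "ess",                        11.5,         4.4,           1.4,         1.3,      0,     24
  )
}

#' Synthetic two-group study specification
#'
#' Generative description of a patient-versus-control resting-state study:
#' group sizes, scan geometry and timing, the clinical covariate
#' distributions, the spatial regions where group-dependent coherence
#' dynamics are injected, and optional couplings between the injected
#' effect and named covariates. One integer seed makes every downstream
#' generator deterministic.
#'
#' Each effect region is a sphere in which all voxels share a common
#' band-limited signal whose mixing weight is amplitude-modulated over
#' time. Controls get modulation depth `base_depth`; patients get
#' `base_depth + sign * amplitude` (clipped to `[0, 0.95]`), so windowed
#' concordance is more (sign +1) or less (sign -1) variable in patients.
#'
#' @param n_patients,n_controls Group sizes (defaults 79 and 84).
#' @param grid_shape Voxel grid, length 3 (default `c(24, 24, 16)`).
#' @param voxel_size_mm Voxel edges in mm (default 3 mm isotropic).
#' @param n_volumes Time points per scan (default 240).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param effect_regions Tibble with columns `x`, `y`, `z` (1-based centre
#'   voxel), `radius` (voxels), `sign` (+1/-1), `amplitude` (modulation-depth
#'   difference between groups). Default: a single positive sphere of radius
#'   3 at the grid centre with amplitude 0.4.
#' @param covariate_params Tibble as returned by [table1_params()].
#' @param coupling Tibble with columns `variable`, `region` (row index into
#'   `effect_regions`), `target_r`: covariates to couple to the subject's
#'   measured injected-region concordance variability (patients only).
#' @param base_depth Control-group modulation depth (default 0.5).
#' @param base_mix Baseline mixing weight of the shared signal relative to
#'   unit-variance voxel noise (default 1).
#' @param envelope `"sine"` or `"boxcar"` modulation envelope.
#' @param envelope_phase `"random"` (subject-specific phase, default) or
#'   `"fixed"` (phase 0 for every subject — a phase-locked, lower-variance
#'   design used by the package's validation experiments).
#' @param envelope_period_tr Envelope period in TR units (default 80).
#' @param subject_effect_sd Between-subject SD of the multiplicative depth
#'   scaling (default 0.25), truncated to `[0.1, 1.9]`.
#' @param analysis_window_length,analysis_window_step Window schedule the
#'   generator uses when it measures a subject's injected-region
#'   concordance variability for covariate coupling (defaults 30 and 1).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 79L, n_controls = 84L,
                        grid_shape = c(24L, 24L, 16L),
                        voxel_size_mm = c(3, 3, 3),
                        n_volumes = 240L, tr_seconds = 2,
                        effect_regions = NULL,
                        covariate_params = table1_params(),
                        coupling = NULL,
                        base_depth = 0.5, base_mix = 1,
                        envelope = c("sine", "boxcar"),
                        envelope_phase = c("random", "fixed"),
                        envelope_period_tr = 80,
                        subject_effect_sd = 0.25,
                        analysis_window_length = 30L,
                        analysis_window_step = 1L,
                        seed = 1L) {
  envelope <- match.arg(envelope)
  envelope_phase <- match.arg(envelope_phase)
  if (n_patients < 1L || n_controls < 1L) {
    stop("group sizes must be positive", call. = FALSE)
  }
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            tr_seconds > 0, n_volumes > 2)
  if (is.null(effect_regions)) {
    effect_regions <- tibble::tibble(
      x = ceiling(grid_shape[1] / 2), y = ceiling(grid_shape[2] / 2),
      z = ceiling(grid_shape[3] / 2), radius = 3, sign = 1, amplitude = 0.4
    )
  }
  effect_regions <- tibble::as_tibble(effect_regions)
  req <- c("x", "y", "z", "radius", "sign", "amplitude")
  if (!all(req %in% names(effect_regions))) {
    stop("effect_regions needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(effect_regions))) {
    r <- effect_regions[i, ]
    ctr <- c(r$x, r$y, r$z)
    if (any(ctr - r$radius < 1) || any(ctr + r$radius > grid_shape)) {
      stop("effect region ", i, " extends outside the grid", call. = FALSE)
    }
    if (!r$sign %in% c(-1, 1)) stop("region sign must be +1 or -1",
                                    call. = FALSE)
    if (r$amplitude < 0) stop("region amplitude must be >= 0", call. = FALSE)
  }
  covariate_params <- tibble::as_tibble(covariate_params)
  if (any(covariate_params$patient_sd < 0) ||
      any(covariate_params$control_sd < 0)) {
    stop("covariate sds must be non-negative", call. = FALSE)
  }
  if (is.null(coupling)) {
    coupling <- tibble::tibble(variable = character(), region = integer(),
                               target_r = numeric())
  }
  coupling <- tibble::as_tibble(coupling)
  if (nrow(coupling) > 0) {
    stopifnot(all(coupling$variable %in% covariate_params$variable),
              all(coupling$region %in% seq_len(nrow(effect_regions))),
              all(abs(coupling$target_r) < 1))
  }
  if (analysis_window_length >= n_volumes) {
    stop("n_volumes must exceed the planned analysis window length",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         effect_regions = effect_regions,
         covariate_params = covariate_params, coupling = coupling,
         base_depth = base_depth, base_mix = base_mix, envelope = envelope,
         envelope_phase = envelope_phase,
         envelope_period_tr = envelope_period_tr,
         subject_effect_sd = subject_effect_sd,
         analysis_window_length = as.integer(analysis_window_length),
         analysis_window_step = as.integer(analysis_window_step),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Generate the clinical covariate table of a synthetic cohort
#'
#' Draws every clinical variable as an independent truncated Gaussian per
#' group from `spec$covariate_params`. Covariates named in `spec$coupling`
#' are re-drawn against the injected imaging effect by [simulate_cohort()];
#' here they receive ordinary uncoupled draws.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `subject_id`, `group` (`"patient"`/`"control"`) and
#'   one column per clinical variable; deterministic given `spec$seed`.
#' @export
generate_clinical_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$covariate_params
  with_rng_seed(derive_seed(spec$seed, "clinical"), {
    draw_group <- function(n, prefix, mean_col, sd_col) {
      cols <- purrr::pmap(
        list(p$variable, p[[mean_col]], p[[sd_col]], p$lower, p$upper),
        function(v, m, s, lo, hi) rtrunc_norm(n, m, s, lo, hi)
      )
      names(cols) <- p$variable
      tibble::tibble(
        subject_id = sprintf("%s%03d", prefix, seq_len(n)),
        group = ifelse(prefix == "P", "patient", "control"),
        !!!cols
      )
    }
    pat <- draw_group(spec$n_patients, "P", "patient_mean", "patient_sd")
    ctl <- draw_group(spec$n_controls, "C", "control_mean", "control_sd")
    dplyr::bind_rows(pat, ctl)
  })
}

#' Generate a per-volume head-motion trace
#'
#' Smooth random-walk traces for the six rigid-body parameters. By default
#' every translation stays strictly below 1.5 mm and every rotation strictly
#' below 1.5 degrees; with `exceed_threshold = TRUE` one randomly chosen
#' parameter is scaled to peak beyond its bound, so the subject fails
#' [motion_screen()].
#'
#' @param record One-row tibble (or list) with at least `subject_id`.
#' @param spec A [cohort_spec()].
#' @param exceed_threshold Force a threshold violation (default FALSE).
#' @return `n_volumes` x 6 matrix, columns `trans_x`, `trans_y`, `trans_z`
#'   (mm), `rot_x`, `rot_y`, `rot_z` (degrees).
#' @export
generate_motion_trace <- function(record, spec, exceed_threshold = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  Tn <- spec$n_volumes
  with_rng_seed(derive_seed(spec$seed, "motion", record$subject_id), {
    m <- matrix(0, Tn, 6)
    peaks <- stats::runif(6, 0.15, 1.2)  # strictly below both 1.5 bounds
    for (j in 1:6) {
      w <- cumsum(stats::rnorm(Tn))
      w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
      w[is.na(w)] <- 0
      mx <- max(abs(w))
      if (mx > 0) w <- w / mx * peaks[j]
      m[, j] <- w
    }
    if (exceed_threshold) {
      j <- sample.int(6, 1)
      mx <- max(abs(m[, j]))
      target <- stats::runif(1, 1.6, 2.5)
      m[, j] <- if (mx > 0) m[, j] / mx * target else
        c(rep(0, Tn - 1), target)
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

region_voxel_index <- function(spec, i) {
  r <- spec$effect_regions[i, ]
  d <- spec$grid_shape
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  dist2 <- (g[, 1] - r$x)^2 + (g[, 2] - r$y)^2 + (g[, 3] - r$z)^2
  which(dist2 <= r$radius^2)
}

subject_depth_multiplier <- function(record, spec) {
  with_rng_seed(derive_seed(spec$seed, "depth", record$subject_id), {
    min(max(stats::rnorm(1, 1, spec$subject_effect_sd), 0.1), 1.9)
  })
}

envelope_series <- function(spec, phase, Tn) {
  t <- seq_len(Tn)
  base <- sin(2 * pi * t / spec$envelope_period_tr + phase)
  if (spec$envelope == "boxcar") base <- sign(base)
  base
}

#' Generate one subject's synthetic 4D scan
#'
#' Baseline voxel series are independent band-limited Gaussian noise (plus a
#' constant offset and a small linear drift, removed again by
#' preprocessing). Inside each effect region, a shared band-limited common
#' signal is mixed in with a time-varying weight
#' `base_mix * (1 + depth * envelope(t))`; the modulation depth depends on
#' the subject's group and the region's sign, so the windowed concordance of
#' the region varies more (or less) over time in patients than in controls.
#'
#' @param record One-row tibble with `subject_id` and `group`.
#' @param spec A [cohort_spec()].
#' @return A list of class `simulated_scan`: `subject_id`, `volume`
#'   ([volume4d()]), `motion_trace`, `ground_truth_effect` (3D array of the
#'   group depth difference, zero outside effect regions), `depth`
#'   (per-region realised modulation depth for this subject).
#' @export
generate_scan <- function(record, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_shape
  Tn <- spec$n_volumes
  V <- prod(d)
  mult <- subject_depth_multiplier(record, spec)
  scan_seed <- derive_seed(spec$seed, "scan", record$subject_id)
  pcfg <- prep_config(n_discard = 0L, detrend = FALSE)
  with_rng_seed(scan_seed, {
    noise <- array(stats::rnorm(V * Tn), dim = c(d, Tn))
    vol <- volume4d(noise, tr_seconds = spec$tr_seconds,
                    voxel_size_mm = spec$voxel_size_mm)
    vol <- bandpass_filter(vol, pcfg)
    dat <- vol$data / stats::sd(vol$data)
    gt <- array(0, dim = d)
    depths <- numeric(nrow(spec$effect_regions))
    for (i in seq_len(nrow(spec$effect_regions))) {
      r <- spec$effect_regions[i, ]
      idx <- region_voxel_index(spec, i)
      group_depth <- spec$base_depth +
        if (record$group == "patient") r$sign * r$amplitude else 0
      depth <- min(max(group_depth * mult, 0), 0.95)
      depths[i] <- depth
      phase <- if (spec$envelope_phase == "fixed") 0 else
        stats::runif(1, 0, 2 * pi)
      common <- stats::rnorm(Tn)
      cv <- volume4d(array(common, dim = c(1, 1, 1, Tn)),
                     tr_seconds = spec$tr_seconds)
      common <- bandpass_filter(cv, pcfg)$data[1, 1, 1, ]
      common <- common / stats::sd(common)
      w <- spec$base_mix * (1 + depth * envelope_series(spec, phase, Tn))
      add <- outer(rep(1, length(idx)), w * common)
      flat <- matrix(dat, nrow = V)
      flat[idx, ] <- flat[idx, ] + add
      dat <- array(flat, dim = c(d, Tn))
      gt[idx] <- gt[idx] + r$sign * r$amplitude
    }
    drift <- stats::rnorm(V, 0, 0.005)
    flat <- matrix(dat, nrow = V) + outer(drift, seq_len(Tn)) + 1000
    dat <- array(flat, dim = c(d, Tn))
    structure(
      list(subject_id = record$subject_id,
           volume = volume4d(dat, tr_seconds = spec$tr_seconds,
                             voxel_size_mm = spec$voxel_size_mm),
           motion_trace = generate_motion_trace(record, spec),
           ground_truth_effect = gt,
           depth = depths),
      class = "simulated_scan"
    )
  })
}

#' @export
print.simulated_scan <- function(x, ...) {
  cat(sprintf("<simulated_scan> subject %s, depth(s) %s\n", x$subject_id,
              paste(signif(x$depth, 3), collapse = ", ")))
  print(x$volume)
  invisible(x)
}

# Windowed-concordance variability of an effect region, measured on the raw
# generated scan: mean over region voxels of the across-window SD of
# Kendall's W, neighbourhoods restricted to the region. Used to couple
# clinical covariates to the realised imaging effect.
region_dreho_sd <- function(scan, spec, region = 1L) {
  idx <- region_voxel_index(spec, region)
  mask <- array(FALSE, dim = spec$grid_shape)
  mask[idx] <- TRUE
  vol <- volume4d(scan$volume$data, tr_seconds = spec$tr_seconds,
                  mask = mask, voxel_size_mm = spec$voxel_size_mm)
  m <- dreho_map(vol, connectivity = 27L,
                 length_tr = spec$analysis_window_length,
                 step_tr = spec$analysis_window_step, metric = "sd")
  mean(mask_values(m))
}

#' Simulate a full two-group study
#'
#' Generates the clinical table, per-subject motion traces, and (optionally)
#' the 4D scans of a cohort. When `spec$coupling` is non-empty, the named
#' covariates of the patient group are re-drawn against each subject's
#' measured injected-region concordance variability, with the noise set so
#' the target correlation holds in expectation.
#'
#' @param spec A [cohort_spec()].
#' @param scans Generate the 4D scans (default TRUE; FALSE returns only the
#'   clinical table and motion traces).
#' @return List of class `simulated_cohort`: `spec`, `clinical` (tibble),
#'   `scans` (named list of `simulated_scan` or NULL), `motion` (named list
#'   of traces).
#' @export
simulate_cohort <- function(spec, scans = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  clinical <- generate_clinical_table(spec)
  records <- split(clinical, seq_len(nrow(clinical)))
  motion <- purrr::map(records, generate_motion_trace, spec = spec)
  names(motion) <- clinical$subject_id
  scan_list <- NULL
  if (scans) {
    scan_list <- purrr::map(records, generate_scan, spec = spec)
    names(scan_list) <- clinical$subject_id
    if (nrow(spec$coupling) > 0) {
      pat <- which(clinical$group == "patient")
      for (ci in seq_len(nrow(spec$coupling))) {
        cp <- spec$coupling[ci, ]
        m <- vapply(scan_list[pat], region_dreho_sd, numeric(1),
                    spec = spec, region = cp$region)
        z <- as.numeric(scale(m))
        pars <- spec$covariate_params[
          spec$covariate_params$variable == cp$variable, ]
        y <- with_rng_seed(
          derive_seed(spec$seed, "coupling", cp$variable), {
            cp$target_r * z +
              sqrt(1 - cp$target_r^2) * stats::rnorm(length(z))
          })
        vals <- pars$patient_mean + pars$patient_sd * y
        clinical[[cp$variable]][pat] <-
          pmin(pmax(vals, pars$lower), pars$upper)
      }
    }
  }
  structure(
    list(spec = spec, clinical = clinical, scans = scan_list,
         motion = motion),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated_cohort> %d patients + %d controls, grid %s, %d volumes%s\n",
    sum(x$clinical$group == "patient"), sum(x$clinical$group == "control"),
    paste(x$spec$grid_shape, collapse = "x"), x$spec$n_volumes,
    if (is.null(x$scans)) " (clinical only)" else ""
  ))
  invisible(x)
}
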