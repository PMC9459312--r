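# Shared fixture builders; everything is generated in code under fixed seeds.

random_volume <- function(dims = c(6, 6, 5), n_t = 24, seed = 1,
                          tr = 2, mask = NULL) {
  withr::with_seed(seed, {
    volume4d(array(rnorm(prod(dims) * n_t), dim = c(dims, n_t)),
             tr_seconds = tr, mask = mask)
  })
}

# Brute-force ReHo: per-voxel Kendall's W over the in-mask neighbourhood,
# computed with the reference kendall_w() and an explicit neighbour search.
brute_reho <- function(vol, connectivity = 27L, t_range = NULL) {
  d <- dim(vol$data)[1:3]
  Tn <- dim(vol$data)[4]
  if (is.null(t_range)) t_range <- seq_len(Tn)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "7" = m <= 1, "19" = m <= 2, "27" = m <= 3), ,
             drop = FALSE]
  out <- array(NA_real_, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!vol$mask[x, y, z]) next
    p <- sweep(off, 2, c(x, y, z), `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    p <- p[ok, , drop = FALSE]
    p <- p[vol$mask[p], , drop = FALSE]
    series <- vapply(seq_len(nrow(p)), function(i) {
      vol$data[p[i, 1], p[i, 2], p[i, 3], t_range]
    }, numeric(length(t_range)))
    out[x, y, z] <- kendall_w(series)
  }
  out
}

# All permutations of 1..n as a list (exhaustive oracle helper).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

tiny_effect_spec <- function(amplitude, seed, n_patients = 2L,
                             n_controls = 2L) {
  cohort_spec(
    n_patients = n_patients, n_controls = n_controls,
    grid_shape = c(10L, 10L, 8L), n_volumes = 100L,
    effect_regions = tibble::tibble(x = 5, y = 5, z = 4, radius = 2,
                                    sign = 1, amplitude = amplitude),
    envelope = "boxcar", envelope_phase = "fixed",
    envelope_period_tr = 40, subject_effect_sd = 0.08, base_mix = 1.2,
    analysis_window_length = 30L, analysis_window_step = 2L,
    seed = seed
  )
}
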