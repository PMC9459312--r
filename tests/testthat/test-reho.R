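test_that("kendall_w reproduces hand-computed and reference values", {
  inc <- matrix(rep(seq_len(10) + 0.3, 27), ncol = 27)
  expect_equal(kendall_w(inc), 1)

  # worked 3 x 4 example: two concordant series, one fully reversed
  expect_equal(kendall_w(cbind(1:4, 1:4, 4:1)), 1 / 9, tolerance = 1e-12)

  expect_error(kendall_w(matrix(1:4, ncol = 1)), "two series")
  expect_error(kendall_w(matrix(1:4, nrow = 1)), "two time points")

  withr::with_seed(42, {
    for (i in 1:8) {
      n <- sample(5:40, 1)
      K <- sample(2:27, 1)
      x <- matrix(rnorm(n * K), n, K)
      if (i %% 2 == 0) x <- matrix(sample(1:4, n * K, TRUE), n, K)  # ties
      ref <- vegan::kendall.global(x)$Concordance_analysis["W", 1]
      expect_equal(kendall_w(x), unname(ref), tolerance = 1e-12)
    }
  })
})

test_that("kendall_w is invariant to strictly monotone per-series transforms", {
  withr::with_seed(1, {
    x <- matrix(rnorm(20 * 6), 20, 6)
    y <- x
    y[, 1] <- exp(x[, 1])
    y[, 2] <- x[, 2]^3
    y[, 3] <- 10 + 2 * x[, 3]
    expect_equal(kendall_w(x), kendall_w(y), tolerance = 1e-12)
  })
})

test_that("null concordance of K independent series averages 1/K", {
  withr::with_seed(7, {
    ws <- replicate(2000, kendall_w(matrix(rnorm(8 * 5), 8, 5)))
  })
  se <- sd(ws) / sqrt(length(ws))
  expect_lt(abs(mean(ws) - 1 / 5), 3 * se)
})

test_that("sliding-window schedules follow the half-open count formula", {
  expect_equal(nrow(sliding_windows(230, 30, 1)), 201L)
  expect_equal(nrow(sliding_windows(230, 25, 1)), 206L)
  w <- sliding_windows(230, 35, 1)
  expect_equal(nrow(w), 196L)
  expect_equal(w$start[1], 0L)
  expect_equal(w$end[nrow(w)], 230L)
  # non-overlapping windows
  expect_equal(nrow(sliding_windows(100, 20, 20)), 5L)
  expect_error(sliding_windows(20, 30, 1), "exceeds")
  expect_error(sliding_windows(100, 20, 25), "step")
})

test_that("reho_map equals per-voxel brute force, including mask edges", {
  mask <- array(TRUE, dim = c(6, 6, 5))
  mask[1, , ] <- FALSE
  mask[3, 4, 2] <- FALSE  # hole in the mask
  vol <- random_volume(dims = c(6, 6, 5), n_t = 20, seed = 31, mask = mask)
  for (conn in c(27L, 19L, 7L)) {
    m <- reho_map(vol, connectivity = conn)
    expect_equal(m$data, brute_reho(vol, conn), tolerance = 1e-12)
  }
  # neighbour counts shrink at edges and are recorded
  m27 <- reho_map(vol, connectivity = 27L)
  expect_equal(max(m27$extra$K), 27L)
  expect_lt(m27$extra$K[2, 1, 1], 27L)
})

test_that("reho_map hits the analytic anchors: shared series and null mean", {
  d <- c(7, 7, 6)
  Tn <- 25
  shared <- withr::with_seed(5, rnorm(Tn))
  vol <- volume4d(array(rep(shared, each = prod(d)), c(d, Tn)),
                  tr_seconds = 2)
  m <- reho_map(vol)
  expect_true(all(abs(mask_values(m) - 1) < 1e-12))

  noise <- random_volume(dims = c(10, 10, 8), n_t = 30, seed = 6)
  mn <- reho_map(noise)
  interior <- mn$data[3:8, 3:8, 3:6]
  expect_lt(abs(mean(interior) - 1 / 27), 0.01)
})

test_that("dreho_map equals a brute-force window loop and validates windows", {
  vol <- random_volume(dims = c(5, 5, 4), n_t = 30, seed = 8)
  m <- dreho_map(vol, length_tr = 10L, step_tr = 5L)
  win <- sliding_windows(30, 10L, 5L)
  per_win <- lapply(seq_len(nrow(win)), function(i) {
    brute_reho(vol, 27L, t_range = (win$start[i] + 1):win$end[i])
  })
  stack <- simplify2array(per_win)
  expect_equal(m$data, apply(stack, 1:3, sd), tolerance = 1e-12)

  mcv <- dreho_map(vol, length_tr = 10L, step_tr = 5L, metric = "cv")
  expect_equal(mcv$data, apply(stack, 1:3, sd) / apply(stack, 1:3, mean),
               tolerance = 1e-12)

  expect_error(dreho_map(vol, length_tr = 30L), "two windows")
})

test_that("normalisation and z-scoring satisfy their definitions", {
  vol <- random_volume(dims = c(6, 6, 4), n_t = 20, seed = 9)
  m <- reho_map(vol)
  nm <- normalize_by_global_mean(m)
  expect_equal(mean(mask_values(nm)), 1, tolerance = 1e-12)

  cm <- scalar_map(array(3.7, c(4, 4, 3)))
  expect_true(all(mask_values(normalize_by_global_mean(cm)) == 1))
  zm0 <- scalar_map(array(0, c(4, 4, 3)))
  expect_error(normalize_by_global_mean(zm0), "zero")

  z <- zscore_map(m)
  expect_equal(mean(mask_values(z)), 0, tolerance = 1e-12)
  expect_equal(sd(mask_values(z)), 1, tolerance = 1e-12)
  aff <- scalar_map(2.5 * m$data + 3, mask = m$mask, affine = m$affine)
  expect_equal(zscore_map(aff)$data, z$data, tolerance = 1e-10)
  expect_error(zscore_map(cm), "zero")
})

test_that("gaussian smoothing preserves constants and respects the mask", {
  mask <- array(TRUE, dim = c(8, 8, 6))
  mask[1:2, 1:3, ] <- FALSE
  cm <- scalar_map(array(2.2, c(8, 8, 6)), mask = mask)
  sm <- gaussian_smooth(cm, 6)
  expect_equal(mask_values(sm), rep(2.2, sum(mask)), tolerance = 1e-12)

  vol <- random_volume(dims = c(8, 8, 6), n_t = 15, seed = 10, mask = mask)
  m <- reho_map(vol)
  expect_identical(gaussian_smooth(m, 0), m)
  sm2 <- gaussian_smooth(m, 6)
  # smoothing shrinks spatial variance but keeps the in-mask mean close
  expect_lt(sd(mask_values(sm2)), sd(mask_values(m)))

  # kernel width: FWHM 6 mm at 3 mm voxels means sigma 0.8493 voxels
  k <- dreho:::gaussian_kernel_1d(6 / (2 * sqrt(2 * log(2))) / 3)
  half <- (length(k) - 1) / 2
  disc_sd <- sqrt(sum(k * (seq(-half, half))^2))
  expect_equal(disc_sd, 0.8493, tolerance = 0.01)
})

test_that("the full dReHo chain reproduces its frozen golden fixture", {
  vol <- random_volume(dims = c(6, 6, 5), n_t = 60, seed = 123)
  m <- dreho_map(vol, length_tr = 20L, step_tr = 4L)
  out <- gaussian_smooth(normalize_by_global_mean(m), 6)
  golden_path <- test_path("golden_dreho_chain.tsv")
  vals <- data.frame(voxel = seq_along(out$data) - 1L,
                     value = sprintf("%.17g", as.numeric(out$data)))
  ref <- read.table(golden_path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character"))
  expect_identical(as.numeric(ref$value), as.numeric(vals$value))
})
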