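make_maps <- function(n, dims = c(6, 6, 5), seed = 1, shift = NULL,
                      group = NULL) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- array(rnorm(prod(dims)), dim = dims)
      if (!is.null(shift) && group[i] == "patient") a <- a + shift
      scalar_map(a)
    })
  })
}

test_that("the GLM t-map equals the closed-form two-sample t when unadjusted", {
  group <- rep(c("patient", "control"), c(7, 9))
  maps <- make_maps(16, seed = 11, shift = 0.5, group = group)
  design <- build_design(tibble::tibble(group = group),
                         covariates = character())
  stat <- voxelwise_glm_ttest(maps, design)
  expect_equal(stat$dof, 14L)

  Y <- sapply(maps, function(m) as.numeric(m$data))
  t_ref <- apply(Y, 1, function(y) {
    unname(t.test(y[group == "patient"], y[group == "control"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(as.numeric(stat$t), t_ref, tolerance = 1e-10)
})

test_that("a covariate orthogonal to group and data only changes the dof", {
  group <- rep(c("patient", "control"), each = 8)
  dims <- c(2, 2, 2)
  maps <- make_maps(16, dims = dims, seed = 12, shift = 0.8, group = group)
  Y <- sapply(maps, function(m) as.numeric(m$data))  # V x n
  g <- as.numeric(group == "patient")
  base <- cbind(1, g, t(Y))
  cov_raw <- withr::with_seed(3, rnorm(16))
  cov_orth <- residuals(lm(cov_raw ~ base))

  d0 <- build_design(tibble::tibble(group = group), character())
  t0 <- voxelwise_glm_ttest(maps, d0)
  clin <- tibble::tibble(group = group, orth = cov_orth)
  d1 <- build_design(clin, "orth")
  t1 <- voxelwise_glm_ttest(maps, d1)
  expect_equal(t1$dof, t0$dof - 1L)
  expect_equal(as.numeric(t1$t), as.numeric(t0$t) *
                 sqrt(t1$dof / t0$dof), tolerance = 1e-8)
})

test_that("null data give a near-zero mean t-map and a full-rank check", {
  group <- rep(c("patient", "control"), each = 10)
  maps <- make_maps(20, seed = 13)
  design <- build_design(tibble::tibble(group = group), character())
  stat <- voxelwise_glm_ttest(maps, design)
  expect_lt(abs(mean(stat$t)), 0.2)
  clin <- tibble::tibble(group = group, dup = as.numeric(group == "patient"))
  expect_error(build_design(clin, "dup"), "rank deficient")
})

test_that("smoothness estimation recovers a known kernel and orders fields", {
  dims <- c(24, 24, 24)
  mask <- array(TRUE, dim = dims)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3  # 6 mm FWHM at 3 mm voxels
  n <- 16
  sm <- withr::with_seed(21, {
    t(sapply(seq_len(n), function(i) {
      as.numeric(dreho:::smooth_3d(array(rnorm(prod(dims)), dims),
                                   rep(sigma, 3)))
    }))
  })
  est <- estimate_smoothness(sm, mask)
  expect_true(all(abs(est$fwhm * 3 - 6) / 6 < 0.15))

  wh <- withr::with_seed(22, {
    t(sapply(seq_len(n), function(i) rnorm(prod(dims))))
  })
  est_wh <- estimate_smoothness(wh, mask)
  expect_true(all(est_wh$fwhm < est$fwhm))
  expect_true(all(est_wh$fwhm < 2))
  expect_gt(est_wh$resels, est$resels)
})

test_that("GRF extent thresholds move monotonically with smoothness and voxel p", {
  stat <- structure(
    list(t = array(0, c(16, 16, 16)), dof = 38L,
         mask = array(TRUE, c(16, 16, 16)), affine = diag(c(3, 3, 3, 1)),
         idx = seq_len(16^3), fwhm = c(2, 2, 2), resels = 16^3 / 8),
    class = "stat_map"
  )
  k1 <- grf_cluster_extent_threshold(stat, voxel_p_tail = 0.005)
  stat2 <- stat
  stat2$fwhm <- c(4, 4, 4)
  stat2$resels <- 16^3 / 64
  k2 <- grf_cluster_extent_threshold(stat2, voxel_p_tail = 0.005)
  expect_gt(k2, k1)

  k3 <- grf_cluster_extent_threshold(stat, voxel_p_tail = 0.0005)
  expect_lt(k3, k1)

  # t-field option gives a (weakly) different, valid threshold
  kt <- grf_cluster_extent_threshold(stat, voxel_p_tail = 0.005,
                                     field = "t")
  expect_gte(kt, 1)
})

test_that("cluster extraction is sign-symmetric, ordered, and exact", {
  dims <- c(12, 12, 10)
  tarr <- array(0, dims)
  tarr[3:5, 3:5, 3:5] <- 5    # positive block, 27 voxels
  tarr[8:10, 8:10, 5:7] <- -6 # negative block
  tarr[6, 6, 9] <- 4          # single voxel, below extent threshold
  stat <- structure(
    list(t = tarr, dof = 30L, mask = array(TRUE, dims),
         affine = diag(c(3, 3, 3, 1)), idx = seq_len(prod(dims))),
    class = "stat_map"
  )
  cl <- extract_clusters(stat, k = 5, voxel_p_tail = 0.005)
  expect_equal(nrow(cl$table), 2L)
  expect_equal(cl$table$sign, c(-1, 1))  # ordered by |peak t|
  expect_equal(cl$table$n_voxels, c(27L, 27L))
  expect_equal(cl$table$peak_t, c(-6, 5))
  # world coordinates from 0-based voxel indices through the affine
  expect_equal(cl$table$peak_x_mm[2], cl$table$peak_i[2] * 3)

  neg <- stat
  neg$t <- -tarr
  cln <- extract_clusters(neg, k = 5, voxel_p_tail = 0.005)
  expect_equal(cln$table$sign, -cl$table$sign)
  expect_equal(cln$table$n_voxels, cl$table$n_voxels)
  expect_equal(cln$table$peak_t, -cl$table$peak_t)

  # connectivity matters: two diagonal blocks merge under 26 but not 6
  tarr2 <- array(0, dims)
  tarr2[3:4, 3:4, 3:4] <- 5
  tarr2[5:6, 5:6, 5:6] <- 5
  stat2 <- stat
  stat2$t <- tarr2
  c26 <- extract_clusters(stat2, k = 5, voxel_p_tail = 0.005,
                          connectivity = 26L)
  c6 <- extract_clusters(stat2, k = 5, voxel_p_tail = 0.005,
                         connectivity = 6L)
  expect_equal(nrow(c26$table), 1L)
  expect_equal(nrow(c6$table), 2L)
})

test_that("cluster means equal brute-force masked averages", {
  dims <- c(8, 8, 6)
  labels <- array(0L, dims)
  labels[2:3, 2:3, 2] <- 1L
  labels[6, 6, 4] <- 2L
  clusters <- structure(
    list(table = tibble::tibble(cluster = 1:2, sign = c(1, -1),
                                n_voxels = c(4L, 1L), peak_t = c(4, -4),
                                peak_i = 0L, peak_j = 0L, peak_k = 0L,
                                peak_x_mm = 0, peak_y_mm = 0, peak_z_mm = 0),
         labels = labels),
    class = "cluster_set"
  )
  maps <- make_maps(5, dims = dims, seed = 31)
  cm <- cluster_means(maps, clusters)
  expect_equal(dim(cm), c(5L, 3L))
  for (i in 1:5) {
    expect_equal(cm$cluster1[i], mean(maps[[i]]$data[labels == 1L]))
    expect_equal(cm$cluster2[i], maps[[i]]$data[6, 6, 4])
  }
  cmap <- scalar_map(array(4.2, dims))
  expect_equal(cluster_means(list(cmap), clusters)$cluster1, 4.2)
})
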