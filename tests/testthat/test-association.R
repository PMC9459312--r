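test_that("summary-based Welch t matches published-table arithmetic", {
  expect_equal(welch_ttest_from_summary(54.0, 21.7, 79, 2.2, 1.2, 84)$t,
               21.19, tolerance = 0.005)
  expect_equal(welch_ttest_from_summary(460.9, 71.6, 79, 441.8, 22.3, 84)$t,
               2.27, tolerance = 0.005)
  same <- welch_ttest_from_summary(10, 2, 30, 10, 2, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_ttest_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("summary-based Welch t equals t.test on the raw vectors", {
  withr::with_seed(14, {
    x <- rnorm(40, 5, 2)
    y <- rnorm(55, 4, 3)
  })
  ours <- welch_ttest_from_summary(mean(x), sd(x), length(x),
                                   mean(y), sd(y), length(y))
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$dof, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("pearson_cor matches anchors, cor.test, and a permutation oracle", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  x <- c(1.5, 2, 4, 4.5, 7)
  expect_equal(pearson_cor(x, -2 * x + 5)$r, -1)

  r4 <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r4$r, 0.8, tolerance = 1e-12)

  withr::with_seed(15, {
    a <- rnorm(20)
    b <- 0.4 * a + rnorm(20)
  })
  ours <- pearson_cor(a, b)
  ref <- cor.test(a, b)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # symmetry and positive-affine invariance
  expect_equal(pearson_cor(b, a)$r, ours$r)
  expect_equal(pearson_cor(3 * a + 1, b)$r, ours$r, tolerance = 1e-12)

  # exhaustive permutation oracle on 7 points: the t-based p should agree
  # with the permutation p to within the oracle's granularity
  x7 <- c(0.2, 1.1, 1.9, 3.2, 4.1, 4.8, 6.0)
  y7 <- c(0.9, 0.4, 2.8, 2.1, 4.9, 4.2, 5.6)
  obs <- pearson_cor(x7, y7)
  perms <- t(sapply(combinat_perms(7), function(p) p))
  r_perm <- apply(perms, 1, function(p) cor(x7, y7[p]))
  p_perm <- mean(abs(r_perm) >= abs(obs$r) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)

  expect_error(pearson_cor(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("clinical scoring rules follow their published definitions", {
  expect_equal(moca_adjust(25, 10), 26)
  expect_equal(moca_adjust(25, 12), 25)
  expect_equal(moca_adjust(30, 10), 30)
  expect_error(moca_adjust(31, 10), "\\[0, 30\\]")

  expect_equal(as.character(classify_ahi(c(54, 20, 2.2, 30, 7))),
               c("severe", "moderate", "normal", "severe", "mild"))
  expect_error(classify_ahi(-1), "non-negative")

  expect_equal(as.character(classify_ess(c(11.5, 6, 24, 3, 16))),
               c("excessive", "normal", "dangerous", "normal", "excessive"))
  expect_error(classify_ess(25), "\\[0, 24\\]")
})

test_that("demographics tables separate groups as generated", {
  spec <- cohort_spec(seed = 33L)
  tab <- generate_clinical_table(spec)
  demo <- demographics_table(tab)
  expect_equal(nrow(demo), nrow(table1_params()))
  expect_equal(demo$variable, table1_params()$variable)
  ahi_t <- demo$t[demo$variable == "ahi"]
  expect_gt(abs(ahi_t), 15)

  # a second seed behaves the same way
  demo2 <- demographics_table(generate_clinical_table(
    cohort_spec(seed = 34L)))
  expect_gt(abs(demo2$t[demo2$variable == "ahi"]), 15)

  # identical groups give t = 0 rows
  dup <- tab[tab$group == "patient", ]
  dup2 <- dup
  dup2$group <- "control"
  dup2$subject_id <- paste0("C", dup2$subject_id)
  both <- rbind(dup, dup2)
  d0 <- demographics_table(both)
  expect_true(all(abs(d0$t) < 1e-10))
})

test_that("cluster-clinical correlation screen recovers a planted signal", {
  withr::with_seed(16, {
    n <- 60
    feat <- tibble::tibble(subject_id = sprintf("P%03d", 1:n),
                           cluster1 = rnorm(n))
    clinical <- tibble::tibble(
      subject_id = feat$subject_id, group = "patient",
      odi = -0.7 * feat$cluster1 + rnorm(n, sd = 0.5),
      age = rnorm(n, 40, 9)
    )
  })
  out <- correlate_clusters(feat, clinical, c("odi", "age"))
  expect_equal(nrow(out), 2L)
  expect_lt(out$r[out$variable == "odi"], -0.5)
  expect_lt(out$p[out$variable == "odi"], 0.05)
  out_adj <- correlate_clusters(feat, clinical, c("odi", "age"),
                                adjust = TRUE)
  expect_true(all(out_adj$p_adj >= out_adj$p - 1e-15))
})
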