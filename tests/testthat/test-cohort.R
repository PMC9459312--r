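test_that("clinical table generation is deterministic and matches its parameters", {
  spec <- cohort_spec(seed = 11L)
  tab1 <- generate_clinical_table(spec)
  tab2 <- generate_clinical_table(spec)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 79 + 84)
  expect_setequal(unique(tab1$group), c("patient", "control"))

  # patient AHI sample mean close to its generating mean (n = 79)
  ahi <- tab1$ahi[tab1$group == "patient"]
  se <- 21.7 / sqrt(79)
  expect_lt(abs(mean(ahi) - 54.0), 3 * se)
  expect_true(all(ahi >= 0))
  # bounded scales stay in range
  expect_true(all(tab1$moca_total >= 0 & tab1$moca_total <= 30))
  expect_true(all(tab1$ess >= 0 & tab1$ess <= 24))
  expect_true(all(tab1$sleep_efficiency <= 100))

  # zero-sd variable degenerates to its mean
  pars <- table1_params()
  pars$patient_sd[pars$variable == "age"] <- 0
  spec0 <- cohort_spec(covariate_params = pars, seed = 3L)
  tab0 <- generate_clinical_table(spec0)
  expect_true(all(tab0$age[tab0$group == "patient"] == 38.5))

  pars$patient_sd[pars$variable == "age"] <- -1
  expect_error(cohort_spec(covariate_params = pars), "non-negative")
  expect_error(cohort_spec(n_patients = 0L), "positive")
})

test_that("generated covariate means converge to spec means (n = 500/group)", {
  spec <- cohort_spec(n_patients = 500L, n_controls = 500L, seed = 21L)
  tab <- generate_clinical_table(spec)
  p <- spec$covariate_params
  for (i in seq_len(nrow(p))) {
    v <- p$variable[i]
    # truncation shifts hard-bounded skewed variables; compare against the
    # expectation of the truncated distribution via its analytic form
    for (grp in c("patient", "control")) {
      m <- if (grp == "patient") p$patient_mean[i] else p$control_mean[i]
      s <- if (grp == "patient") p$patient_sd[i] else p$control_sd[i]
      a <- (p$lower[i] - m) / s
      b <- (p$upper[i] - m) / s
      trunc_mean <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
      x <- tab[[v]][tab$group == grp]
      expect_lt(abs(mean(x) - trunc_mean), 0.2 * s)
    }
  }
})

test_that("motion traces respect the 1.5 mm / 1.5 degree construction bounds", {
  spec <- cohort_spec(n_volumes = 120L, seed = 5L)
  rec <- list(subject_id = "P001")
  tr <- generate_motion_trace(rec, spec)
  expect_equal(nrow(tr), 120L)
  expect_equal(ncol(tr), 6L)
  expect_lt(max(abs(tr[, 1:3])), 1.5)
  expect_lt(max(abs(tr[, 4:6])), 1.5)
  expect_identical(tr, generate_motion_trace(rec, spec))

  bad <- generate_motion_trace(rec, spec, exceed_threshold = TRUE)
  expect_false(motion_screen(bad)$retained)
  expect_true(motion_screen(tr)$retained)
})

test_that("scan generation is seeded-deterministic with faithful ground truth", {
  spec <- tiny_effect_spec(amplitude = 0.3, seed = 9L)
  rec <- tibble::tibble(subject_id = "P001", group = "patient")
  s1 <- generate_scan(rec, spec)
  s2 <- generate_scan(rec, spec)
  expect_identical(s1$volume$data, s2$volume$data)

  region <- dreho:::region_voxel_index(spec, 1L)
  gt <- s1$ground_truth_effect
  expect_true(all(gt[region] == 0.3))
  expect_true(all(gt[-region] == 0))
  expect_equal(nrow(s1$motion_trace), spec$n_volumes)
  expect_error(
    cohort_spec(effect_regions = tibble::tibble(x = 1, y = 5, z = 4,
                                                radius = 3, sign = 1,
                                                amplitude = 0.2)),
    "outside the grid"
  )
})

test_that("injected modulation raises windowed-concordance variability monotonically", {
  # Monte-Carlo oracle over repeated small cohorts: patient-minus-control
  # region dReHo-sd averaged over seeds must be positive and increase with
  # the injected depth difference. Cohorts are paired across depths (same
  # seed, hence identical noise and common-signal realisations), so the
  # comparison isolates the depth effect.
  depths <- c(0.1, 0.25, 0.4)
  n_rep <- 20L
  diffs <- sapply(depths, function(a) {
    mean(sapply(seq_len(n_rep), function(i) {
      spec <- tiny_effect_spec(a, seed = 100L + 17L * i)
      cohort <- simulate_cohort(spec)
      m <- vapply(cohort$scans, dreho:::region_dreho_sd, numeric(1),
                  spec = spec)
      grp <- cohort$clinical$group
      mean(m[grp == "patient"]) - mean(m[grp == "control"])
    }))
  })
  expect_true(all(diffs > 0))
  expect_true(all(diff(diffs) > 0))
})

test_that("coupled covariates reach their target correlation in expectation", {
  # sleep period time is far from its truncation bound, so the target
  # correlation is not attenuated by clipping; small-sample correlation
  # bias at n = 30 is well inside the tolerance
  n_rep <- 50L
  rs <- sapply(seq_len(n_rep), function(i) {
    spec <- tiny_effect_spec(0.3, seed = 300L + i, n_patients = 30L,
                             n_controls = 2L)
    spec$coupling <- tibble::tibble(variable = "sleep_period_time",
                                    region = 1L, target_r = -0.5)
    cohort <- simulate_cohort(spec)
    pat <- cohort$clinical$group == "patient"
    m <- vapply(cohort$scans[pat], dreho:::region_dreho_sd, numeric(1),
                spec = spec)
    cor(m, cohort$clinical$sleep_period_time[pat])
  })
  expect_lt(abs(mean(rs) - (-0.5)), 0.05)
})
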