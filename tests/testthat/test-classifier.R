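test_that("confusion metrics follow their definitions exactly", {
  truth <- rep(c("patient", "control"), c(79, 84))
  pred <- rep(c("patient", "control", "patient", "control"),
              c(64, 15, 15, 69))
  m <- confusion_metrics(truth, pred)
  expect_equal(round(m$accuracy, 2), 81.60)
  expect_equal(round(m$precision, 2), 81.01)
  expect_equal(round(m$sensitivity, 2), 81.01)
  expect_equal(round(m$specificity, 2), 82.14)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(64, 15, 69, 15))

  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity")]),
               c(accuracy = 100, precision = 100, sensitivity = 100,
                 specificity = 100))

  allpos <- confusion_metrics(truth, rep("patient", length(truth)))
  expect_equal(allpos$sensitivity, 100)
  expect_equal(allpos$specificity, 0)
  expect_error(confusion_metrics(character(), character()), "empty")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  withr::with_seed(17, {
    truth <- rep(c("patient", "control"), c(25, 30))
    scores <- rnorm(55) + (truth == "patient") * 0.8
    scores[3] <- scores[30]  # introduce a tie across classes
  })
  r <- roc_auc(scores, truth)
  u <- suppressWarnings(wilcox.test(scores[truth == "patient"],
                                    scores[truth == "control"])$statistic)
  expect_equal(r$auc, unname(u) / (25 * 30), tolerance = 1e-12)

  sep <- roc_auc(c(rep(2, 10), rep(-2, 12)),
                 rep(c("patient", "control"), c(10, 12)))
  expect_equal(sep$auc, 1)
  expect_error(roc_auc(1:5, rep("patient", 5)), "both classes")
})

test_that("LOOCV separates well-separated blobs and counts its folds", {
  withr::with_seed(18, {
    X <- rbind(matrix(rnorm(20 * 2, mean = 5, sd = 0.3), 20),
               matrix(rnorm(24 * 2, mean = -5, sd = 0.3), 24))
  })
  labels <- rep(c("patient", "control"), c(20, 24))
  fit <- loocv_linear_svm(X, labels)
  expect_equal(fit$metrics$accuracy, 100)
  expect_equal(fit$auc, 1)
  expect_equal(nrow(fit$folds), 44L)
  expect_equal(fit$folds$truth, labels)
})

test_that("permuted labels drive LOOCV accuracy to the majority rate", {
  withr::with_seed(19, {
    X <- matrix(rnorm(16 * 2), 16)
    base <- rep(c("patient", "control"), c(9, 7))
    accs <- replicate(40, {
      lab <- sample(base)
      loocv_linear_svm(X, lab)$metrics$accuracy
    })
  })
  # chance level for 9/7 split; LOOCV is pessimistically biased under the
  # null, so the band is wide but must exclude systematic skill
  expect_lt(mean(accs), 62)
  expect_gt(mean(accs), 30)
})

test_that("label flips swap sensitivity/specificity and mirror the AUC", {
  withr::with_seed(20, {
    X <- rbind(matrix(rnorm(12 * 2, 1.2), 12), matrix(rnorm(12 * 2), 12))
  })
  labels <- rep(c("patient", "control"), each = 12)
  a <- loocv_linear_svm(X, labels, positive = "patient")
  b <- loocv_linear_svm(X, labels, positive = "control")
  expect_equal(a$metrics$sensitivity, b$metrics$specificity)
  expect_equal(a$metrics$specificity, b$metrics$sensitivity)
  # with the score orientation held fixed, swapping the positive class
  # mirrors the AUC
  flipped <- roc_auc(a$folds$score, labels, positive = "control")
  expect_equal(flipped$auc, 1 - a$auc, tolerance = 1e-12)
})

test_that("fold-wise standardisation makes metrics scale invariant", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(10 * 2, 1), 10), matrix(rnorm(10 * 2), 10))
  })
  labels <- rep(c("patient", "control"), each = 10)
  a <- loocv_linear_svm(X, labels)
  X2 <- X
  X2[, 1] <- X2[, 1] * 1000 + 5
  b <- loocv_linear_svm(X2, labels)
  expect_equal(a$metrics, b$metrics, tolerance = 1e-6)
  expect_equal(a$auc, b$auc, tolerance = 1e-6)
})

test_that("tidy and glance expose folds and headline metrics", {
  withr::with_seed(24, {
    X <- rbind(matrix(rnorm(8 * 2, 3), 8), matrix(rnorm(8 * 2, -3), 8))
  })
  labels <- rep(c("patient", "control"), each = 8)
  fit <- loocv_linear_svm(X, labels)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("subject_id", "truth", "score", "predicted"))
  gl <- glance(fit)
  expect_equal(gl$n, 16L)
  expect_equal(gl$accuracy, 100)
  expect_s3_class(tidy(fit$roc), "tbl_df")
  # a constant feature is dropped with a warning, not an error
  Xc <- cbind(X, 1)
  suppressWarnings(expect_warning(fitc <- loocv_linear_svm(Xc, labels),
                                  "constant"))
  expect_equal(fitc$metrics$accuracy, fit$metrics$accuracy)
})
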