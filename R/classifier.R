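#' Confusion-matrix performance metrics
#'
#' Standard rates with the patient class positive: sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/n`, all expressed as percentages.
#'
#' @param truth,predicted Vectors of labels (`"patient"`/`"control"`, or any
#'   two levels with `positive` naming the positive one).
#' @param positive Positive-class label (default `"patient"`).
#' @return One-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity` (percent), plus the confusion counts `tp`, `fn`, `tn`,
#'   `fp`.
#' @examples
#' confusion_metrics(rep(c("patient", "control"), c(79, 84)),
#'                   rep(c("patient", "control", "patient", "control"),
#'                       c(64, 15, 15, 69)))
#' @export
confusion_metrics <- function(truth, predicted, positive = "patient") {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    accuracy = pct(tp + tn, length(truth)),
    precision = pct(tp, tp + fp),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' ROC curve and area under it
#'
#' Threshold sweep over the decision scores (higher score = more
#' patient-like); the area is computed by the trapezoid rule, which with
#' rank-averaged ties equals the Mann–Whitney U statistic divided by
#' `n1 * n2`.
#'
#' @param scores Numeric decision scores.
#' @param truth Labels; `positive` is the positive class.
#' @param positive Positive-class label (default `"patient"`).
#' @return List of class `roc_curve`: `curve` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "patient") {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(th) {
    tibble::tibble(threshold = th,
                   fpr = sum(scores >= th & !pos) / n2,
                   tpr = sum(scores >= th & pos) / n1)
  })
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

# Fit a linear soft-margin SVM and return a signed decision function
# (positive = patient side). Standardisation statistics come from the
# training fold only.
fit_linear_svm <- function(X, y, C = 1, standardize = TRUE,
                           positive = "patient") {
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all features are constant in a training fold",
                       call. = FALSE)
  if (any(!keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  ctr <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  yf <- factor(ifelse(y == positive, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = C, scale = FALSE)
  # e1071's decision value sign depends on the first class seen in training;
  # orient it so positive values mean the positive class.
  flip <- if (fit$labels[1] == which(levels(yf) == "pos")) 1 else -1
  function(newX) {
    newX <- newX[, keep, drop = FALSE]
    ns <- sweep(sweep(newX, 2L, ctr), 2L, scl, `/`)
    pr <- stats::predict(fit, ns, decision.values = TRUE)
    drop(attr(pr, "decision.values")) * flip
  }
}

#' Leave-one-out cross-validated linear SVM
#'
#' For each subject, a soft-margin linear support-vector machine is trained
#' on the remaining n - 1 subjects (features standardised with
#' training-fold statistics only) and the held-out subject is predicted
#' from the signed decision score. Performance metrics are pooled over all
#' folds and the ROC is built from the pooled scores.
#'
#' @param features Numeric matrix or tibble (a `subject_id` column, if
#'   present, is used for labelling rows) of subjects x features.
#' @param labels Character vector of class labels.
#' @param C Soft-margin cost (default 1).
#' @param standardize Standardise features within each training fold
#'   (default TRUE).
#' @param positive Positive-class label (default `"patient"`).
#' @return Object of class `svm_loocv`: `metrics` (from
#'   [confusion_metrics()]), `auc`, `roc` ([roc_auc()] result), `folds`
#'   (tibble with per-fold `subject_id`, `truth`, `score`, `predicted`).
#' @export
loocv_linear_svm <- function(features, labels, C = 1, standardize = TRUE,
                             positive = "patient") {
  ids <- NULL
  if (is.data.frame(features)) {
    if ("subject_id" %in% names(features)) {
      ids <- features$subject_id
      features <- features[setdiff(names(features), "subject_id")]
    }
    features <- as.matrix(features)
  }
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_len(n))
  if (min(table(labels)) < 2L) {
    stop("need at least two subjects per class", call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%d", seq_len(ncol(features)))
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    dec <- fit_linear_svm(features[-i, , drop = FALSE], labels[-i], C = C,
                          standardize = standardize, positive = positive)
    scores[i] <- dec(features[i, , drop = FALSE])
  }
  predicted <- ifelse(scores > 0, positive,
                      setdiff(unique(labels), positive)[1])
  roc <- roc_auc(scores, labels, positive = positive)
  structure(
    list(metrics = confusion_metrics(labels, predicted, positive = positive),
         auc = roc$auc, roc = roc,
         folds = tibble::tibble(subject_id = ids, truth = labels,
                                score = scores, predicted = predicted)),
    class = "svm_loocv"
  )
}

#' @export
print.svm_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<svm_loocv> %d folds | accuracy %.2f%%, precision %.2f%%, ",
    "sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n"),
    nrow(x$folds), m$accuracy, m$precision, m$sensitivity, m$specificity,
    x$auc))
  invisible(x)
}

#' Fully nested leave-one-out SVM with per-fold cluster selection
#'
#' Unlike [loocv_linear_svm()] on group-defined cluster means — which
#' inherits the selection circularity of defining features on the full
#' sample — this variant re-runs the whole group inference (GLM, smoothness,
#' GRF extent threshold, cluster extraction) on each training fold of n - 1
#' subjects, computes cluster-mean features from that fold's clusters only,
#' and predicts the held-out subject. Folds whose training data yield no
#' surviving cluster fall back to a zero decision score (majority-side
#' prediction by the sign convention).
#'
#' @param maps Named list of per-subject [scalar_map()]s.
#' @param clinical Clinical tibble with `subject_id`, `group` and the
#'   nuisance covariates.
#' @param covariates Nuisance covariates for the per-fold design.
#' @param voxel_p,cluster_p,connectivity,field Inference settings, as in
#'   [group_inference()].
#' @param C,standardize,positive Classifier settings, as in
#'   [loocv_linear_svm()].
#' @return An object of class `svm_loocv` (same shape as
#'   [loocv_linear_svm()]), with an extra `n_empty_folds` field counting
#'   folds without surviving clusters.
#' @export
nested_loocv_svm <- function(maps, clinical,
                             covariates = c("age", "education",
                                            "motion_summary"),
                             voxel_p = 0.01, cluster_p = 0.05,
                             connectivity = 26L, field = "gaussian",
                             C = 1, standardize = TRUE,
                             positive = "patient") {
  ids <- clinical$subject_id
  stopifnot(!is.null(names(maps)), all(ids %in% names(maps)))
  maps <- maps[ids]
  labels <- clinical$group
  n <- length(ids)
  negative <- setdiff(unique(labels), positive)[1]
  scores <- numeric(n)
  empty <- 0L
  for (i in seq_len(n)) {
    train_clin <- clinical[-i, ]
    inf <- group_inference(maps[-i], build_design(train_clin, covariates),
                           voxel_p = voxel_p, cluster_p = cluster_p,
                           connectivity = connectivity, field = field)
    if (nrow(inf$clusters$table) == 0L) {
      empty <- empty + 1L
      scores[i] <- 0
      next
    }
    feats <- cluster_means(maps[-i], inf$clusters, subject_ids = ids[-i])
    X <- as.matrix(feats[-1])
    dec <- fit_linear_svm(X, labels[-i], C = C, standardize = standardize,
                          positive = positive)
    test_feat <- vapply(inf$clusters$table$cluster, function(ci) {
      mean(maps[[i]]$data[inf$clusters$labels == ci])
    }, numeric(1))
    scores[i] <- dec(matrix(test_feat, nrow = 1,
                            dimnames = list(NULL, colnames(X))))
  }
  predicted <- ifelse(scores > 0, positive, negative)
  roc <- roc_auc(scores, labels, positive = positive)
  structure(
    list(metrics = confusion_metrics(labels, predicted,
                                     positive = positive),
         auc = roc$auc, roc = roc,
         folds = tibble::tibble(subject_id = ids, truth = labels,
                                score = scores, predicted = predicted),
         n_empty_folds = empty),
    class = "svm_loocv"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.svm_loocv <- function(x, ...) x$folds

#' @export
glance.svm_loocv <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$metrics, "accuracy", "precision",
                              "sensitivity", "specificity"),
                auc = x$auc, n = nrow(x$folds))
}

#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$curve))
}
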