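#' Welch's two-sample t-test from group summaries
#'
#' Unequal-variance t-statistic computed from printed group means, SDs and
#' sizes, with Welch–Satterthwaite degrees of freedom and a two-sided p
#' value. This is the test that reproduces published demographic-table
#' t-values from their summary rows.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @return One-row tibble: `t`, `dof`, `p`.
#' @examples
#' welch_ttest_from_summary(54.0, 21.7, 79, 2.2, 1.2, 84)  # t = 21.19
#' @export
welch_ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  dof <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, dof = dof,
                 p = 2 * stats::pt(abs(t), dof, lower.tail = FALSE))
}

#' Pearson correlation with t-based p value
#'
#' Sample Pearson r and the two-sided p value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-zero variance.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Education-adjusted MoCA score
#'
#' One point is added to the raw Montreal Cognitive Assessment total when
#' the subject has fewer than 12 years of education, capped at the scale
#' maximum of 30.
#'
#' @param raw_total Raw MoCA total in `[0, 30]`.
#' @param education_years Years of education.
#' @return Adjusted score.
#' @export
moca_adjust <- function(raw_total, education_years) {
  if (any(raw_total < 0 | raw_total > 30)) {
    stop("raw MoCA total must be in [0, 30]", call. = FALSE)
  }
  pmin(raw_total + as.numeric(education_years < 12), 30)
}

#' Apnoea–hypopnoea index severity category
#'
#' `normal` below 5 events/h, `mild` 5 to <15, `moderate` 15 to <30,
#' `severe` above 30. An AHI of exactly 30 is assigned to `severe` (the
#' conventional band edges leave 30 itself uncovered; assigning it upward
#' is the stricter reading).
#'
#' @param ahi Events per hour, >= 0.
#' @return Factor with levels normal, mild, moderate, severe.
#' @export
classify_ahi <- function(ahi) {
  if (any(ahi < 0)) stop("ahi must be non-negative", call. = FALSE)
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Epworth Sleepiness Scale category
#'
#' Strict bands: a score greater than 6 indicates drowsiness, greater than
#' 11 excessive drowsiness, greater than 16 dangerous drowsiness.
#'
#' @param score ESS score in `[0, 24]`.
#' @return Factor with levels normal, drowsy, excessive, dangerous.
#' @export
classify_ess <- function(score) {
  if (any(score < 0 | score > 24)) {
    stop("ESS score must be in [0, 24]", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 6, 11, 16, Inf), right = TRUE,
      labels = c("normal", "drowsy", "excessive", "dangerous"))
}

#' Group comparison table of clinical variables
#'
#' One row per clinical variable: group means and SDs plus the Welch t and
#' p value computed from the raw per-subject values. Row order follows the
#' column order of the input table.
#'
#' @param clinical Tibble with `group` and numeric clinical columns.
#' @param variables Variables to compare; defaults to every numeric column
#'   except identifiers.
#' @return Tibble: `variable`, `patient_mean`, `patient_sd`, `control_mean`,
#'   `control_sd`, `t`, `dof`, `p`.
#' @export
demographics_table <- function(clinical, variables = NULL) {
  stopifnot("group" %in% names(clinical))
  pat <- clinical[clinical$group == "patient", ]
  ctl <- clinical[clinical$group == "control", ]
  if (nrow(pat) == 0L || nrow(ctl) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(clinical)[vapply(clinical, is.numeric,
                                                logical(1))],
                         c("subject_id", "group"))
  }
  purrr::map_dfr(variables, function(v) {
    x <- pat[[v]]
    y <- ctl[[v]]
    if (anyNA(x) || anyNA(y)) stop("missing values in ", v, call. = FALSE)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble::tibble(variable = v, patient_mean = mean(x),
                            patient_sd = 0, control_mean = mean(y),
                            control_sd = 0, t = 0, dof = NA_real_, p = 1))
    }
    w <- welch_ttest_from_summary(mean(x), stats::sd(x), length(x),
                                  mean(y), stats::sd(y), length(y))
    tibble::tibble(variable = v, patient_mean = mean(x),
                   patient_sd = stats::sd(x), control_mean = mean(y),
                   control_sd = stats::sd(y), t = w$t, dof = w$dof, p = w$p)
  })
}

#' Correlate cluster-mean dReHo with clinical variables
#'
#' Pearson screen between each cluster-mean column and each clinical
#' variable, within the patient group (the group in which clinical
#' heterogeneity is of interest). P values are uncorrected by default; a
#' Benjamini–Hochberg adjusted column is added when `adjust = TRUE`.
#'
#' @param features Tibble from [cluster_means()] (`subject_id` +
#'   `cluster<i>` columns).
#' @param clinical Clinical tibble with `subject_id`, `group` and variables.
#' @param variables Clinical variables to screen.
#' @param group Which group to correlate within (default `"patient"`).
#' @param adjust Add BH-adjusted p values (default FALSE).
#' @return Tibble: `cluster`, `variable`, `r`, `p`, `n` (+ `p_adj`).
#' @export
correlate_clusters <- function(features, clinical, variables,
                               group = "patient", adjust = FALSE) {
  df <- dplyr::inner_join(features, clinical, by = "subject_id")
  df <- df[df$group == group, ]
  cl_cols <- grep("^cluster", names(features), value = TRUE)
  out <- purrr::map_dfr(cl_cols, function(cc) {
    purrr::map_dfr(variables, function(v) {
      res <- pearson_cor(df[[cc]], df[[v]])
      tibble::tibble(cluster = cc, variable = v, r = res$r, p = res$p,
                     n = res$n)
    })
  })
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
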