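#' Leave-one-out cross-validated probabilities
#'
#' For each subject, fits the logistic model on the remaining n - 1
#' subjects and records the fitted probability of the held-out subject.
#' By default the variable set is fixed (the model selected once on the
#' full data); `selection_in_fold = TRUE` re-runs backward stepwise
#' selection inside every training fold, the stricter variant. Folds in
#' which the fit does not converge or separates are flagged and scored
#' with the last stable iterate rather than aborted.
#'
#' @param cohort `cohort_table` containing `label` and the model variables.
#' @param model_variables character vector of predictor columns.
#' @param selection_in_fold re-select variables within each fold.
#' @param p_enter,p_remove stepwise thresholds used when
#'   `selection_in_fold` is `TRUE`.
#' @return data frame with `subject_id`, `label`, `prob` (out-of-fold
#'   probability of being invasive) and `flagged`.
#' @export
loocv_probabilities <- function(cohort, model_variables,
                                selection_in_fold = FALSE,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(inherits(cohort, "data.frame"))
  n <- nrow(cohort)
  if (n < 10L) stop("leave-one-out needs at least 10 subjects", call. = FALSE)
  if (min(table(factor(cohort$label, levels = 0:1))) < 2L)
    stop("each class needs at least 2 subjects so every training fold ",
         "contains both classes", call. = FALSE)
  missing_vars <- setdiff(model_variables, names(cohort))
  if (length(missing_vars))
    stop("variables not in cohort: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  prob <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    test <- cohort[i, , drop = FALSE]
    res <- tryCatch({
      vars <- model_variables
      if (selection_in_fold) {
        sel <- backward_stepwise(train[, model_variables, drop = FALSE],
                                 train$label, p_enter, p_remove)
        vars <- sel$selected
        fit <- sel$fit
      } else {
        fit <- logistic_fit(train[, vars, drop = FALSE], train$label)
      }
      list(p = predict(fit, test), flag = !fit$converged)
    }, error = function(e) {
      # separation or non-convergence in this fold: score with the
      # unchecked IRLS iterate and flag
      dat <- cbind(train[, model_variables, drop = FALSE], .y = train$label)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = dat, family = stats::binomial()))
      list(p = unname(stats::predict(fit, newdata = test,
                                     type = "response")),
           flag = TRUE)
    })
    prob[i] <- res$p
    flagged[i] <- res$flag
  }
  data.frame(subject_id = if ("subject_id" %in% names(cohort))
    cohort$subject_id else as.character(seq_len(n)),
    label = cohort$label, prob = prob, flagged = flagged)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by threshold sweep (convention: score >= threshold
#' predicts invasive) and estimates the AUC by the Mann-Whitney
#' pair-counting statistic with ties counted 1/2, with a DeLong 95%
#' confidence interval.
#'
#' @param scores numeric risk scores, higher = more invasive-like.
#' @param labels binary 0/1 outcomes.
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `curve` (data frame fpr/tpr/threshold), `scores`, `labels`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  r <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                      threshold = r$thresholds)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 curve = curve, scores = scores, labels = labels),
            class = "roc_result")
}

# placement values: per-case mean of [case > control] (+ 1/2 ties), and
# per-control analogue
placements <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp),
       auc = mean(cmp))
}

#' DeLong comparison of two correlated AUCs
#'
#' Placement-value variance/covariance estimator for two risk scores on
#' the same subjects, with a two-sided z-test for the AUC difference and
#' 95% confidence intervals for each AUC and for the difference.
#'
#' @param scoresA,scoresB paired numeric scores on identical subjects.
#' @param labels binary 0/1 outcomes.
#' @return list with `aucA`, `aucB`, `varA`, `varB`, `covAB`, `delta`
#'   (`aucA - aucB`), `ci_low`, `ci_high` (for the difference), `z`, `p`.
#' @export
delong_compare <- function(scoresA, scoresB, labels) {
  labels <- as.numeric(labels)
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("scores must be paired with labels (equal lengths)", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  pa <- placements(scoresA, labels)
  pb <- placements(scoresB, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(1 - pa$v01, 1 - pb$v01))
  S <- s10 / m + s01 / n
  varA <- S[1, 1]; varB <- S[2, 2]; covAB <- S[1, 2]
  delta <- pa$auc - pb$auc
  vd <- varA + varB - 2 * covAB
  if (vd <= .Machine$double.eps) {
    z <- 0; p <- 1; half <- 0
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
    half <- stats::qnorm(0.975) * sqrt(vd)
  }
  list(aucA = pa$auc, aucB = pb$auc, varA = varA, varB = varB,
       covAB = covAB, delta = delta, ci_low = delta - half,
       ci_high = delta + half, z = z, p = p)
}

#' Agreement band for an ICC value
#'
#' `<= 0.40` poor, `(0.40, 0.60]` moderate, `(0.60, 0.80]` good,
#' `> 0.80` excellent.
#'
#' @param icc intraclass correlation (at most 1).
#' @return category string.
#' @export
banding <- function(icc) {
  stopifnot(icc <= 1)
  if (icc <= 0.40) "poor"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "good"
  else "excellent"
}

#' Two-way random-effects absolute-agreement ICC (single rater)
#'
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with
#' mean squares from the two-way subjects-by-raters ANOVA; the confidence
#' interval is the standard F-based interval. Absolute agreement penalizes
#' systematic rater offsets, unlike the consistency form.
#'
#' @param ratings n-subjects by k-raters numeric matrix, no missing cells.
#' @param level confidence level (default 0.95).
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `msr`,
#'   `msc`, `mse`, `n`, `k`, `category`, `flagged`.
#' @export
icc_agreement <- function(ratings, level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("ICC needs at least 5 subjects", call. = FALSE)
  if (k < 2L) stop("ICC needs at least 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("missing cells are not allowed", call. = FALSE)
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < .Machine$double.eps) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, msr = msr, msc = msc,
                          mse = mse, n = n, k = k,
                          category = NA_character_, flagged = TRUE),
                     class = "icc_result"))
  }
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom
  alpha <- 1 - level
  if (mse < .Machine$double.eps && msc < .Machine$double.eps) {
    lo <- hi <- 1  # perfect agreement, degenerate F interval
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, msr = msr,
                 msc = msc, mse = mse, n = n, k = k,
                 category = banding(min(icc, 1)), flagged = FALSE),
            class = "icc_result")
}

#' Per-feature inter-rater ICC table
#'
#' Joins two feature tables (one per reader) on `subject_id` and computes
#' the absolute-agreement ICC with its band for every shared feature
#' column.
#'
#' @param features_a,features_b data frames with `subject_id` and feature
#'   columns (as written by [write_feature_table()]).
#' @param features feature columns to compare; defaults to the five shape
#'   features present in both tables.
#' @return data frame with `feature`, `icc`, `ci_low`, `ci_high`,
#'   `category`.
#' @export
icc_table <- function(features_a, features_b, features = NULL) {
  if (is.null(features))
    features <- intersect(
      intersect(c("log_volume", "surface_area_cm2", "sphericity",
                  "discrete_compactness", "roundness"), names(features_a)),
      names(features_b))
  only_a <- setdiff(features_a$subject_id, features_b$subject_id)
  only_b <- setdiff(features_b$subject_id, features_a$subject_id)
  if (length(only_a) || length(only_b))
    stop("subject_id mismatch between readers; only in A: ",
         paste(only_a, collapse = ", "), "; only in B: ",
         paste(only_b, collapse = ", "), call. = FALSE)
  b <- features_b[match(features_a$subject_id, features_b$subject_id), ]
  rows <- lapply(features, function(f) {
    r <- icc_agreement(cbind(features_a[[f]], b[[f]]))
    data.frame(feature = f, icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, category = r$category)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample size to establish a correlation coefficient
#'
#' Fisher-z approximation:
#' `n = ceil(((z_alpha + z_power) / atanh(rho0))^2 + 3)`, floored at 4.
#' With the defaults (rho0 = 0.60, alpha = 0.05 one-sided, power = 0.80)
#' this gives n = 16; the two-sided variant gives 20.
#'
#' @param rho0 target correlation, in (0, 1).
#' @param alpha type-I error probability.
#' @param power desired power (1 - beta).
#' @param sided `"one"` (default) or `"two"`.
#' @param max_n guard against tiny `rho0` driving n unbounded.
#' @return required number of subjects (integer).
#' @export
sample_size_correlation <- function(rho0 = 0.60, alpha = 0.05, power = 0.80,
                                    sided = c("one", "two"), max_n = 1e6) {
  sided <- match.arg(sided)
  stopifnot(rho0 > 0, rho0 < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  z_a <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  z_b <- stats::qnorm(power)
  n <- ceiling(((z_a + z_b) / atanh(rho0))^2 + 3)
  if (n > max_n)
    stop("required sample size exceeds ", max_n,
         " (rho0 too close to 0)", call. = FALSE)
  max(4L, as.integer(n))
}
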