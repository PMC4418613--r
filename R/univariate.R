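#' Build a 2x2 contingency table from a cohort
#'
#' Rows are class (encapsulated, invasive), columns are factor
#' (present, absent).
#'
#' @param cohort a `cohort_table`.
#' @param variable name of a binary 0/1 column.
#' @return 2x2 integer matrix with dimnames.
#' @export
contingency_2x2 <- function(cohort, variable) {
  v <- cohort[[variable]]
  if (is.null(v)) stop("no such variable: ", variable, call. = FALSE)
  if (!all(v %in% c(0, 1))) stop(variable, " is not binary", call. = FALSE)
  tab <- matrix(c(sum(cohort$label == 0 & v == 1),
                  sum(cohort$label == 0 & v == 0),
                  sum(cohort$label == 1 & v == 1),
                  sum(cohort$label == 1 & v == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(class = c("encapsulated", "invasive"),
                                factor = c("present", "absent")))
  tab
}

#' Wald odds ratio from a 2x2 table
#'
#' Cross-product odds ratio oriented so that "factor present predicts
#' invasive": with rows (encapsulated, invasive) and columns (present,
#' absent), `OR = (invasive&present * encapsulated&absent) /
#' (invasive&absent * encapsulated&present)`. The Wald interval is
#' `exp(log OR +/- z * SE)` with `SE = sqrt(sum of reciprocal cells)`.
#' Zero cells get the Haldane-Anscombe 0.5 correction, flagged in the
#' result.
#'
#' @param tab 2x2 matrix as from [contingency_2x2()], rows = class
#'   (encapsulated, invasive), columns = (present, absent).
#' @param level confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`,
#'   `corrected`.
#' @examples
#' # encapsulated 3 present / 20 absent; invasive 16 present / 14 absent
#' tab <- matrix(c(3, 20, 16, 14), nrow = 2, byrow = TRUE)
#' odds_ratio_wald(tab)  # OR 7.619, CI 1.861-31.196
#' @export
odds_ratio_wald <- function(tab, level = 0.95) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin: odds ratio undefined", call. = FALSE)
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[2, 1] * t2[1, 2]) / (t2[2, 2] * t2[1, 1])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       log_or = log(or), se_log_or = se, corrected = corrected)
}

#' Association test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction when all expected
#' cell counts are at least 5, otherwise Fisher's exact test (two-sided,
#' point-probability method). Returns which test fired.
#'
#' @param tab 2x2 contingency matrix.
#' @return list with `statistic` (NA for Fisher), `p`, `test_name`,
#'   `min_expected`.
#' @export
association_test <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: empty margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < 5) {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, test_name = "fisher",
         min_expected = min(expected))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         test_name = "chisq", min_expected = min(expected))
  }
}

#' Two-sample t-test
#'
#' Two-sided Student's t-test, pooled variance by default (Welch via
#' `equal_var = FALSE`).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param equal_var pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Univariate screen of cohort variables
#'
#' For each variable: binary 0/1 variables get an association test on
#' their 2x2 table against class; continuous variables get a pooled
#' two-sample t-test. Per-class summaries are counts (binary) or
#' mean +/- SD (continuous). Constant variables are flagged with p = 1.
#'
#' @param cohort a `cohort_table` with both classes present.
#' @param variables character vector of column names; defaults to all
#'   clinical and shape columns present.
#' @return data frame with one row per variable: `variable`, `type`,
#'   `test`, `statistic`, `p`, `enc_summary`, `inv_summary`, `flagged`.
#' @export
univariate_screen <- function(cohort, variables = NULL) {
  stopifnot(inherits(cohort, "data.frame"))
  if (!all(c(0, 1) %in% cohort$label))
    stop("both classes must be present", call. = FALSE)
  if (is.null(variables))
    variables <- intersect(c("age", "symptoms", "myasthenia", "cystic_change",
                             "calcification", "diameter", "log_volume",
                             "surface_area_cm2", "sphericity",
                             "discrete_compactness", "roundness"),
                           names(cohort))
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars))
    stop("variables not in cohort: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    enc <- x[cohort$label == 0]; inv <- x[cohort$label == 1]
    if (length(unique(x)) == 1L) {
      return(data.frame(variable = v, type = "constant", test = "none",
                        statistic = NA_real_, p = 1,
                        enc_summary = format(enc[1]),
                        inv_summary = format(inv[1]), flagged = TRUE))
    }
    if (all(x %in% c(0, 1))) {
      at <- association_test(contingency_2x2(cohort, v))
      data.frame(variable = v, type = "categorical", test = at$test_name,
                 statistic = at$statistic, p = at$p,
                 enc_summary = sprintf("%d/%d", sum(enc), length(enc)),
                 inv_summary = sprintf("%d/%d", sum(inv), length(inv)),
                 flagged = FALSE)
    } else {
      tt <- two_sample_t(enc, inv)
      data.frame(variable = v, type = "continuous", test = "t",
                 statistic = tt$t, p = tt$p,
                 enc_summary = sprintf("%.3f ± %.3f", mean(enc), stats::sd(enc)),
                 inv_summary = sprintf("%.3f ± %.3f", mean(inv), stats::sd(inv)),
                 flagged = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
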