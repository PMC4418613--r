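#' Default variable sets for the three discrimination models
#'
#' The analysis fits three separate logistic models: clinical + CT
#' features alone, 3D shape features alone, and their combination.
#'
#' @return named list of character vectors (`clinical`, `shape`,
#'   `combined`).
#' @export
default_model_variables <- function() {
  clinical <- c("age", "symptoms", "myasthenia", "cystic_change",
                "calcification", "diameter")
  shape <- c("log_volume", "surface_area_cm2", "sphericity",
             "discrete_compactness", "roundness")
  list(clinical = clinical, shape = shape, combined = c(clinical, shape))
}

#' Run the full three-model discrimination analysis
#'
#' Pipeline: univariate screen of every candidate variable; for each of
#' the three models, backward stepwise logistic regression over the
#' variables passing the screen at `screen_threshold`; collinearity check
#' via VIF; leave-one-out cross-validated probabilities; ROC per model;
#' pairwise DeLong comparisons of the cross-validated AUCs. A model whose
#' screen leaves no candidates is reported as intercept-only with a
#' warning.
#'
#' @param cohort a `cohort_table` with `label` and the model variables.
#' @param model_variables named list of candidate variable vectors;
#'   defaults to [default_model_variables()] filtered to available
#'   columns.
#' @param screen_threshold univariate p-value gate for model entry
#'   (default 0.10).
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10).
#' @param vif_limit VIF above which a collinearity warning is recorded
#'   (default 10).
#' @param selection_in_fold re-run selection inside each LOOCV fold.
#' @return list of class `shape_analysis`: `screen`, `models` (per model:
#'   `candidates`, `stepwise`, `odds_ratios`, `vif`, `loocv`, `roc`),
#'   `comparisons` (pairwise DeLong), `thresholds`.
#' @export
run_shape_analysis <- function(cohort, model_variables = NULL,
                               screen_threshold = 0.10,
                               p_enter = 0.05, p_remove = 0.10,
                               vif_limit = 10,
                               selection_in_fold = FALSE) {
  stopifnot(inherits(cohort, "data.frame"))
  if (is.null(model_variables)) {
    model_variables <- lapply(default_model_variables(),
                              intersect, y = names(cohort))
  }
  if (!length(model_variables) || any(!lengths(model_variables)))
    stop("every model needs a non-empty candidate variable list",
         call. = FALSE)
  all_vars <- unique(unlist(model_variables))
  screen <- univariate_screen(cohort, all_vars)
  models <- lapply(names(model_variables), function(mname) {
    vars <- model_variables[[mname]]
    cand <- screen$variable[screen$variable %in% vars &
                              screen$p < screen_threshold & !screen$flagged]
    if (!length(cand))
      warning("model '", mname, "': no variables pass the univariate ",
              "screen; reporting intercept-only", call. = FALSE)
    sw <- backward_stepwise(cohort[, cand, drop = FALSE], cohort$label,
                            p_enter = p_enter, p_remove = p_remove)
    vifs <- if (length(sw$selected) >= 2L)
      vif(cohort[, sw$selected, drop = FALSE]) else NULL
    if (!is.null(vifs) && any(vifs > vif_limit))
      warning("model '", mname, "': VIF above ", vif_limit, " for ",
              paste(names(vifs)[vifs > vif_limit], collapse = ", "),
              call. = FALSE)
    loocv <- loocv_probabilities(
      cohort, if (length(sw$selected)) sw$selected else cand,
      selection_in_fold = selection_in_fold,
      p_enter = p_enter, p_remove = p_remove)
    fit <- sw$fit
    ors <- if (length(sw$selected)) data.frame(
      variable = sw$selected,
      adjusted_or = unname(fit$or[sw$selected]),
      ci_low = unname(fit$ci_low[sw$selected]),
      ci_high = unname(fit$ci_high[sw$selected]),
      p = unname(fit$p[sw$selected])) else
        data.frame(variable = character(), adjusted_or = numeric(),
                   ci_low = numeric(), ci_high = numeric(), p = numeric())
    list(name = mname, candidates = cand, stepwise = sw,
         odds_ratios = ors, vif = vifs, loocv = loocv,
         roc = roc_auc(loocv$prob, loocv$label))
  })
  names(models) <- names(model_variables)
  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  comparisons <- lapply(pairs, function(pr) {
    dl <- delong_compare(models[[pr[1]]]$loocv$prob,
                         models[[pr[2]]]$loocv$prob, cohort$label)
    c(list(model_a = pr[1], model_b = pr[2]), dl)
  })
  structure(list(screen = screen, models = models,
                 comparisons = comparisons,
                 thresholds = list(screen = screen_threshold,
                                   p_enter = p_enter, p_remove = p_remove,
                                   vif_limit = vif_limit)),
            class = "shape_analysis")
}

#' @export
print.shape_analysis <- function(x, ...) {
  cat("<shape_analysis>\n\nUnivariate screen:\n")
  print(x$screen[, c("variable", "test", "p", "enc_summary", "inv_summary")])
  for (m in x$models) {
    cat(sprintf("\nModel '%s': AUC %.3f (95%% CI %.3f-%.3f); selected: %s\n",
                m$name, m$roc$auc, m$roc$ci_low, m$roc$ci_high,
                if (length(m$stepwise$selected))
                  paste(m$stepwise$selected, collapse = ", ")
                else "(intercept only)"))
    if (nrow(m$odds_ratios)) print(m$odds_ratios, row.names = FALSE)
  }
  cat("\nPairwise AUC comparisons (DeLong):\n")
  for (cp in x$comparisons)
    cat(sprintf("  %s vs %s: dAUC %+.3f, p = %.4g\n",
                cp$model_a, cp$model_b, cp$delta, cp$p))
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the screen table as CSV and the model/comparison results as a
#' JSON report mirroring the usual layout (screen table; per-model
#' retained variables with adjusted ORs and CIs; AUCs with CIs; pairwise
#' AUC differences with p-values).
#'
#' @param analysis a `shape_analysis` object.
#' @param dir output directory (created if absent).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "shape_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  screen_path <- file.path(dir, "univariate_screen.csv")
  utils::write.csv(analysis$screen, screen_path, row.names = FALSE)
  report <- list(
    thresholds = analysis$thresholds,
    models = lapply(analysis$models, function(m) list(
      name = m$name, candidates = m$candidates,
      selected = m$stepwise$selected,
      odds_ratios = m$odds_ratios,
      auc = m$roc$auc, auc_ci = c(m$roc$ci_low, m$roc$ci_high),
      loocv_flagged_folds = sum(m$loocv$flagged))),
    comparisons = lapply(analysis$comparisons, function(cp)
      cp[c("model_a", "model_b", "aucA", "aucB", "delta",
           "ci_low", "ci_high", "z", "p")])
  )
  json_path <- file.path(dir, "analysis_report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(screen_path, json_path))
}
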