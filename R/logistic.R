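#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (IRLS), with odds ratios and Wald confidence intervals per
#' coefficient. Continuous predictors are standardized internally for
#' numerical stability and coefficients are back-transformed to the
#' original scale for reporting. Near-complete separation is detected
#' (any standardized coefficient exceeding 15 in absolute value) and
#' raised as an error naming the offending variable, since a diverging
#' coefficient has no finite maximum-likelihood estimate.
#'
#' @param X data frame or matrix of predictors (no intercept column); may
#'   have zero columns for an intercept-only model.
#' @param y binary 0/1 outcome vector (1 = invasive).
#' @param level confidence level for the Wald intervals.
#' @param on_separation `"error"` (default) aborts; `"warn"` keeps the
#'   last IRLS iterate, warns, and marks the fit `separated` — used by
#'   the selection and cross-validation loops, where near-separation
#'   (a huge odds ratio with a very wide interval) must be surfaced but
#'   must not abort the whole analysis.
#' @return object of class `logistic_fit`: `coefficients`, `se`,
#'   `or` (`exp(coef)`), `ci_low`, `ci_high`, `z`, `p`, `loglik`,
#'   `fitted`, `converged`, `n_iter`, `variables`, `n`, plus the data
#'   (`X`, `y`) for nested-model tests.
#' @export
logistic_fit <- function(X, y, level = 0.95,
                         on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y has a single class; logistic model undefined", call. = FALSE)
  if (is.null(X)) X <- data.frame(row.names = seq_along(y))
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (ncol(X) > 0) {
    constant <- vapply(X, function(col) length(unique(col)) == 1L, logical(1))
    if (any(constant))
      stop("constant predictor column(s): ",
           paste(names(X)[constant], collapse = ", "), call. = FALSE)
    if (length(y) <= ncol(X) + 1L)
      stop("need n > number of parameters", call. = FALSE)
  }
  # standardize non-binary columns; remember transforms for back-mapping
  center <- stats::setNames(rep(0, ncol(X)), names(X))
  scale_ <- stats::setNames(rep(1, ncol(X)), names(X))
  Xs <- X
  for (v in names(X)) {
    if (!all(X[[v]] %in% c(0, 1))) {
      center[v] <- mean(X[[v]]); scale_[v] <- stats::sd(X[[v]])
      Xs[[v]] <- (X[[v]] - center[v]) / scale_[v]
    }
  }
  dat <- cbind(Xs, .y = y)
  # IRLS diagnostics (separation, convergence) are reported through the
  # result object; glm's own warnings would duplicate them
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta_std <- stats::coef(fit)
  big <- names(beta_std)[abs(beta_std) > 15 & names(beta_std) != "(Intercept)"]
  separated <- length(big) > 0
  if (separated) {
    msg <- paste0("near-complete separation detected for: ",
                  paste(gsub("`", "", big), collapse = ", "))
    if (on_separation == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  se_std <- sqrt(diag(stats::vcov(fit)))
  nm <- names(X)
  # back-transform to the original predictor scale
  beta <- beta_std
  se <- se_std
  for (v in nm) {
    key <- if (v %in% names(beta)) v else paste0("`", v, "`")
    beta[key] <- beta_std[key] / scale_[v]
    se[key] <- se_std[key] / scale_[v]
  }
  slope_keys <- setdiff(names(beta), "(Intercept)")
  beta["(Intercept)"] <- beta_std["(Intercept)"] -
    sum(beta_std[slope_keys] * center[nm] / scale_[nm])
  names(beta) <- c("(Intercept)", nm)[seq_along(beta)]
  names(se) <- names(beta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    coefficients = beta, se = se, or = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    z = beta / se, p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = as.numeric(stats::logLik(fit)),
    fitted = unname(stats::fitted(fit)),
    converged = fit$converged, n_iter = fit$iter, separated = separated,
    variables = nm, n = length(y), X = X, y = y, glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, logLik=%.3f, %s in %d IRLS iterations\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- data.frame(coef = x$coefficients, se = x$se, or = x$or,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Predict probabilities from a logistic fit
#' @param object a `logistic_fit`.
#' @param newdata data frame containing the fit's variables.
#' @param ... unused.
#' @return fitted probabilities of class 1.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  eta <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (v in object$variables)
    eta <- eta + object$coefficients[[v]] * newdata[[v]]
  1 / (1 + exp(-eta))
}

#' Likelihood-ratio test between nested logistic fits
#'
#' `LR = 2 (ll_full - ll_reduced)`, compared to a chi-square with degrees
#' of freedom equal to the parameter difference.
#'
#' @param full,reduced `logistic_fit` objects on the same data, with the
#'   reduced model's variables a subset of the full model's.
#' @return list with `lr`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n || !identical(full$y, reduced$y))
    stop("models were fit on different data", call. = FALSE)
  if (!all(reduced$variables %in% full$variables))
    stop("models are not nested", call. = FALSE)
  df <- length(full$variables) - length(reduced$variables)
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  list(lr = lr, df = df,
       p = if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Backward stepwise selection with LRT removal
#'
#' Starts from the model containing every candidate, repeatedly removes
#' the variable whose likelihood-ratio test against the current model has
#' the largest p-value above `p_remove`, and after each removal allows an
#' excluded variable back in if its entry LRT p-value is below `p_enter`.
#' Terminates when no removal or re-entry changes the model. Deterministic:
#' ties are broken by candidate order, so input order can affect the trace
#' but not, generically, the final model.
#'
#' @param X data frame of candidate predictors (callers typically pass the
#'   variables surviving a univariate screen at p < 0.1).
#' @param y binary 0/1 outcome.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return list of class `stepwise_result`: `fit` (final `logistic_fit`),
#'   `selected`, `trace` (step, action, variable, lrt, p), `p_enter`,
#'   `p_remove`, `flagged` (TRUE when the result is intercept-only).
#' @export
backward_stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  stopifnot(p_enter > 0, p_enter <= 1, p_remove >= 0, p_remove <= 1)
  X <- as.data.frame(X)
  candidates <- names(X)
  trace <- data.frame(step = integer(), action = character(),
                      variable = character(), lrt = numeric(), p = numeric())
  if (length(candidates) == 0L) {
    return(structure(list(fit = logistic_fit(NULL, y), selected = character(),
                          trace = trace, p_enter = p_enter,
                          p_remove = p_remove, flagged = TRUE),
                     class = "stepwise_result"))
  }
  current <- candidates
  # entries may not recreate a model state already visited; together with
  # the finite state space this guarantees termination even at extreme
  # thresholds (p_remove = 0 walks down to the intercept-only model)
  state_key <- function(vars) paste(sort(vars), collapse = "|")
  visited <- state_key(current)
  fit_for <- function(vars)
    logistic_fit(if (length(vars)) X[, vars, drop = FALSE] else NULL, y,
                 on_separation = "warn")
  cur_fit <- fit_for(current)
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > (length(candidates) + 2L)^3) break  # hard stop, unreachable
    changed <- FALSE
    # removal: variable with the largest LRT p above threshold
    if (length(current)) {
      drops <- lapply(current, function(v) {
        red <- fit_for(setdiff(current, v))
        lrt <- likelihood_ratio_test(cur_fit, red)
        list(v = v, lrt = lrt, fit = red)
      })
      ps <- vapply(drops, function(d) d$lrt$p, numeric(1))
      worst <- which.max(ps)   # first max = candidate order tie-break
      if (ps[worst] > p_remove) {
        v <- drops[[worst]]$v
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         variable = v,
                                         lrt = drops[[worst]]$lrt$lr,
                                         p = ps[worst]))
        cur_fit <- drops[[worst]]$fit
        current <- setdiff(current, v)
        visited <- union(visited, state_key(current))
        changed <- TRUE
      }
    }
    # re-entry: excluded variable with the smallest entry p below threshold
    excluded <- setdiff(candidates, current)
    if (!changed && length(excluded)) {
      adds <- lapply(excluded, function(v) {
        big <- fit_for(c(current, v))
        list(v = v, lrt = likelihood_ratio_test(big, cur_fit), fit = big)
      })
      ps <- vapply(adds, function(a) a$lrt$p, numeric(1))
      blocked <- vapply(adds, function(a)
        state_key(c(current, a$v)) %in% visited, logical(1))
      ps[blocked] <- Inf
      best <- which.min(ps)
      if (is.finite(ps[best]) && ps[best] < p_enter) {
        v <- adds[[best]]$v
        trace <- rbind(trace, data.frame(step = step, action = "enter",
                                         variable = v,
                                         lrt = adds[[best]]$lrt$lr,
                                         p = ps[best]))
        cur_fit <- adds[[best]]$fit
        current <- c(current, v)
        visited <- union(visited, state_key(current))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(fit = cur_fit, selected = current, trace = trace,
                 p_enter = p_enter, p_remove = p_remove,
                 flagged = length(current) == 0L),
            class = "stepwise_result")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of predictor j on the other predictors. Exact collinearity
#' yields `Inf`.
#'
#' @param X data frame or matrix with at least two predictor columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("vif needs at least 2 predictors", call. = FALSE)
  vapply(names(X), function(v) {
    r2 <- summary(stats::lm(X[[v]] ~ .,
                            data = X[, setdiff(names(X), v),
                                     drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}
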