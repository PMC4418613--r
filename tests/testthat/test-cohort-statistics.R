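test_that("Wald odds ratio reproduces closed forms", {
  # encapsulated 3/20, invasive 16/14 with the factor present
  tab <- matrix(c(3, 20, 16, 14), nrow = 2, byrow = TRUE)
  res <- odds_ratio_wald(tab)
  expect_equal(res$or, (16 * 20) / (14 * 3))
  expect_equal(res$or, 7.619, tolerance = 1e-3)
  expect_equal(res$ci_low, 1.861, tolerance = 1e-3)
  expect_equal(res$ci_high, 31.196, tolerance = 1e-4)

  bal <- odds_ratio_wald(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(bal$or, 1.0)
  expect_equal(log(bal$ci_low), -log(bal$ci_high))

  ones <- odds_ratio_wald(matrix(c(1, 1, 1, 1), 2))
  expect_equal(ones$se_log_or, 2.0)
  expect_equal(ones$ci_high, exp(stats::qnorm(0.975) * 2))

  zero <- odds_ratio_wald(matrix(c(0, 5, 5, 5), 2, byrow = TRUE))
  expect_true(zero$corrected)
  expect_error(odds_ratio_wald(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("association test picks chi-square or Fisher by expected counts", {
  tab <- matrix(c(3, 20, 16, 14), nrow = 2, byrow = TRUE)
  res <- association_test(tab)
  expect_equal(res$test_name, "chisq")
  # chi-square computed from first principles
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected))
  expect_lt(res$p, 0.01)

  flat <- association_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  sparse <- association_test(matrix(c(1, 4, 4, 1), 2, byrow = TRUE))
  expect_equal(sparse$test_name, "fisher")
  expect_lt(sparse$min_expected, 5)
  # all expected counts exactly 5: the chi-square branch still applies
  edge <- association_test(matrix(c(1, 9, 9, 1), 2, byrow = TRUE))
  expect_equal(edge$min_expected, 5)
  expect_equal(edge$test_name, "chisq")

  expect_error(association_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("pooled t-test matches the textbook formula", {
  x <- c(4.1, 5.0, 5.5, 4.7, 5.2)
  y <- c(6.3, 5.9, 7.1, 6.6, 6.0)
  res <- two_sample_t(x, y)
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$t, t_manual)
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * stats::pt(-abs(t_manual), 8))

  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  far <- two_sample_t(rnorm(30), rnorm(30) + 10)
  expect_lt(far$p, 1e-10)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("univariate screen recomputes the printed-count contrasts", {
  co <- counts_cohort()                       # cystic change 3/23 vs 16/30
  co$calcification <- counts_cohort(enc_present = 4,
                                    inv_present = 7)$cystic_change
  scr <- univariate_screen(co, c("cystic_change", "calcification"))
  expect_lt(scr$p[scr$variable == "cystic_change"], 0.05)
  expect_gt(scr$p[scr$variable == "calcification"], 0.5)
  expect_equal(scr$enc_summary[scr$variable == "cystic_change"], "3/23")
  expect_equal(scr$inv_summary[scr$variable == "cystic_change"], "16/30")
})

test_that("screen keeps its type-I rate near alpha under label shuffles", {
  set.seed(202)
  co <- simulate_cohort(seed = 202)
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    sh <- co
    sh$label <- sample(sh$label)
    scr <- univariate_screen(sh, c("age", "diameter", "sphericity"))
    hits <- hits + sum(scr$p < 0.05)
  }
  rate <- hits / (3 * reps)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
  # and no shuffled variable should reach extreme significance routinely
  expect_lt(rate, 0.15)
})

test_that("constant covariates are flagged rather than tested", {
  co <- counts_cohort()
  co$flat <- 1
  scr <- univariate_screen(co, c("cystic_change", "flat"))
  expect_true(scr$flagged[scr$variable == "flat"])
  expect_equal(scr$p[scr$variable == "flat"], 1)
})

test_that("logistic slope OR equals the 2x2 cross-product OR", {
  co <- counts_cohort()
  fit <- logistic_fit(co[, "cystic_change", drop = FALSE], co$label)
  orw <- odds_ratio_wald(contingency_2x2(co, "cystic_change"))
  expect_equal(unname(fit$or["cystic_change"]), orw$or, tolerance = 1e-6)
  expect_equal(unname(fit$ci_low["cystic_change"]), orw$ci_low,
               tolerance = 1e-4)
  expect_equal(unname(fit$ci_high["cystic_change"]), orw$ci_high,
               tolerance = 1e-4)

  for (s in 1:50) {
    set.seed(s)
    cells <- rpois(4, 12) + 1
    coh <- counts_cohort(n_enc = cells[1] + cells[2],
                         n_inv = cells[3] + cells[4],
                         enc_present = cells[1], inv_present = cells[3])
    f <- logistic_fit(coh[, "cystic_change", drop = FALSE], coh$label)
    o <- odds_ratio_wald(contingency_2x2(coh, "cystic_change"))
    expect_equal(unname(f$or["cystic_change"]), o$or, tolerance = 1e-6)
    expect_equal(unname(f$ci_low["cystic_change"]), o$ci_low,
                 tolerance = 1e-3)
  }
})

test_that("intercept-only fit recovers the logit of the prevalence", {
  y <- rep(c(0, 1), c(23, 30))
  fit <- logistic_fit(NULL, y)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               stats::qlogis(30 / 53), tolerance = 1e-8)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_lte(fit$loglik, 0)
})

test_that("null predictors produce small z and near-null deviance", {
  set.seed(99)
  x <- data.frame(a = rnorm(120), b = rbinom(120, 1, 0.4))
  y <- rbinom(120, 1, 0.5)
  fit <- logistic_fit(x, y)
  null_fit <- logistic_fit(NULL, y)
  expect_true(all(abs(fit$z[c("a", "b")]) < 3))
  expect_lt(2 * (fit$loglik - null_fit$loglik), stats::qchisq(0.999, 2))
})

test_that("separation is detected and named, or surfaced as a warning", {
  x <- data.frame(sep = c(rep(0, 20), rep(1, 20)), noise = rnorm(40))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_fit(x, y), "sep")
  expect_warning(fit <- logistic_fit(x, y, on_separation = "warn"),
                 "separation")
  expect_true(fit$separated)
  expect_error(logistic_fit(data.frame(k = rep(1, 10)), rep(0:1, 5)),
               "constant")
})

test_that("likelihood-ratio test equals the deviance difference", {
  set.seed(11)
  x <- data.frame(strong = rnorm(200), weak = rnorm(200))
  y <- rbinom(200, 1, stats::plogis(2 * x$strong))
  full <- logistic_fit(x, y)
  red <- logistic_fit(x[, "weak", drop = FALSE], y)
  lrt <- likelihood_ratio_test(full, red)
  expect_lt(lrt$p, 0.001)
  expect_equal(lrt$df, 1)
  # oracle: glm deviance difference on the same data
  d_full <- stats::glm(y ~ strong + weak, data = x,
                       family = stats::binomial())$deviance
  d_red <- stats::glm(y ~ weak, data = x,
                      family = stats::binomial())$deviance
  expect_equal(lrt$lr, d_red - d_full, tolerance = 1e-6)

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$lr, 0)
  expect_equal(same$p, 1)
  other <- logistic_fit(data.frame(z = rnorm(200)), y)
  expect_error(likelihood_ratio_test(full, other), "nested")
})

test_that("stepwise respects its thresholds at both extremes", {
  set.seed(5)
  x <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  y <- rbinom(100, 1, stats::plogis(1.5 * x$x1))
  expect_setequal(backward_stepwise(x, y, p_remove = 1)$selected,
                  c("x1", "x2"))
  expect_length(backward_stepwise(x, y, p_remove = 0)$selected, 0)

  single <- backward_stepwise(x[, "x1", drop = FALSE], y)
  expect_equal(single$selected, "x1")
  expect_equal(nrow(single$trace), 0)

  empty <- backward_stepwise(x[, character(0)], y)
  expect_true(empty$flagged)
  expect_length(empty$fit$variables, 0)
})

test_that("stepwise drops null candidates in most replicates", {
  kept <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- data.frame(n1 = rnorm(200), n2 = rbinom(200, 1, 0.5))
    y <- rbinom(200, 1, 0.5)
    res <- backward_stepwise(x, y)
    if (length(res$selected) == 0L) kept <- kept + 1L
  }
  expect_gte(kept, 12L)
})

test_that("removed variables all exceeded the removal threshold", {
  set.seed(31)
  x <- data.frame(a = rnorm(150), b = rnorm(150), c = rbinom(150, 1, 0.5))
  y <- rbinom(150, 1, stats::plogis(1.2 * x$a))
  res <- backward_stepwise(x, y)
  removed <- res$trace[res$trace$action == "remove", ]
  if (nrow(removed)) expect_true(all(removed$p > res$p_remove))
})

test_that("VIF matches the 1/(1 - R^2) definition", {
  set.seed(8)
  ortho <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  v <- vif(ortho)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-9)

  x1 <- rnorm(200)
  coll <- data.frame(x1 = x1, x2 = x1 + rnorm(200, sd = 1e-4))
  expect_true(all(vif(coll) > 1e4))

  # three equicorrelated Gaussians, rho = 0.5
  set.seed(12)
  z <- rnorm(500)
  X <- data.frame(a = sqrt(0.5) * z + sqrt(0.5) * rnorm(500),
                  b = sqrt(0.5) * z + sqrt(0.5) * rnorm(500),
                  c = sqrt(0.5) * z + sqrt(0.5) * rnorm(500))
  v3 <- vif(X)
  r2_oracle <- summary(stats::lm(a ~ b + c, data = X))$r.squared
  expect_equal(unname(v3["a"]), 1 / (1 - r2_oracle), tolerance = 1e-9)
  expect_equal(unname(v3["a"]), 4 / 3, tolerance = 0.1 / 1.33)
  expect_error(vif(X[, 1, drop = FALSE]), "2 predictors")
})

test_that("IRLS log-likelihood is non-decreasing over iterations", {
  set.seed(21)
  dat <- data.frame(x = rnorm(80), w = rbinom(80, 1, 0.5))
  dat$y <- rbinom(80, 1, stats::plogis(1.3 * dat$x - 0.5 * dat$w))
  ll <- sapply(1:6, function(k) {
    fit <- suppressWarnings(
      stats::glm(y ~ x + w, data = dat, family = stats::binomial(),
                 control = stats::glm.control(maxit = k, epsilon = 1e-14)))
    as.numeric(stats::logLik(fit))
  })
  expect_true(all(diff(ll) > -1e-8))
})
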