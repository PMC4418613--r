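test_that("LOOCV emits one out-of-fold probability per subject", {
  co <- counts_cohort()                       # 53 subjects, cystic only
  res <- loocv_probabilities(co, "cystic_change")
  expect_equal(nrow(res), 53)
  # leaving one subject out can only shift the fit through (class, status),
  # so at most 4 distinct probabilities exist
  expect_lte(length(unique(round(res$prob, 12))), 4)
  # bit-for-bit repeatability with a fixed model
  res2 <- loocv_probabilities(co, "cystic_change")
  expect_identical(res$prob, res2$prob)
})

test_that("LOOCV saturates on a separable feature and stays null on noise", {
  set.seed(3)
  n <- 30
  co <- as_cohort(data.frame(
    subject_id = as.character(1:n), label = rep(0:1, each = n / 2),
    marker = c(rnorm(n / 2, 0), rnorm(n / 2, 12))))
  res <- suppressWarnings(loocv_probabilities(co, "marker"))
  expect_equal(roc_auc(res$prob, res$label)$auc, 1.0)
  expect_true(all(res$prob[co$label == 1] > 0.9))

  # under the null, pooled out-of-fold scores are pessimistically biased
  # (the held-out subject pulls the refit away from itself), so the mean
  # LOOCV AUC sits below 0.5; the key property is the absence of optimism
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    con <- as_cohort(data.frame(subject_id = as.character(1:n),
                                label = rep(0:1, each = n / 2),
                                noise = rnorm(n)))
    r <- loocv_probabilities(con, "noise")
    roc_auc(r$prob, r$label)$auc
  })
  expect_lt(mean(aucs), 0.55)
})

test_that("LOOCV preconditions are enforced", {
  co <- counts_cohort()
  expect_error(loocv_probabilities(co[1:8, ], "cystic_change"), "at least 10")
  solo <- co; solo$label <- c(0L, rep(1L, 52))
  expect_error(loocv_probabilities(solo, "cystic_change"), "2 subjects")
  expect_error(loocv_probabilities(co, "nope"), "not in cohort")
})

test_that("AUC equals brute-force pair counting", {
  r <- roc_auc(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(rep(0.7, 10), rep(0:1, 5))$auc, 0.5)

  for (s in 1:25) {
    set.seed(s)
    scores <- round(rnorm(40), 1)             # rounding forces ties
    labels <- rep(0:1, each = 20)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "classes")
})

test_that("ROC curve is monotone and AUC is rank-invariant", {
  set.seed(9)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, stats::plogis(scores))
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
})

test_that("DeLong comparison agrees with an independent implementation", {
  set.seed(14)
  labels <- rep(0:1, each = 40)
  sA <- rnorm(80) + labels
  sB <- rnorm(80) + 0.4 * labels
  dl <- delong_compare(sA, sB, labels)
  rt <- pROC::roc.test(pROC::roc(labels, sA, quiet = TRUE, direction = "<"),
                       pROC::roc(labels, sB, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p, rt$p.value, tolerance = 1e-9)
  expect_equal(dl$z, unname(rt$statistic), tolerance = 1e-9)
  expect_equal(dl$aucA, brute_auc(sA, labels))

  same <- delong_compare(sA, sA, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_error(delong_compare(sA[-1], sB, labels), "paired")
})

test_that("against constant scores DeLong reduces to the one-AUC z-test", {
  set.seed(15)
  labels <- rep(0:1, each = 30)
  sA <- rnorm(60) + 0.8 * labels
  dl <- delong_compare(sA, rep(0.5, 60), labels)
  expect_equal(dl$aucB, 0.5)
  expect_equal(dl$varB, 0)
  expect_equal(dl$covAB, 0)
  expect_equal(dl$z, (dl$aucA - 0.5) / sqrt(dl$varA))
})

test_that("DeLong variance is consistent with a bootstrap", {
  set.seed(77)
  labels <- rep(0:1, each = 60)
  scores <- rnorm(120) + 0.7 * labels
  dl <- delong_compare(scores, rep(0, 120), labels)
  boots <- replicate(1000, {
    i0 <- sample(which(labels == 0), replace = TRUE)
    i1 <- sample(which(labels == 1), replace = TRUE)
    brute_auc(scores[c(i0, i1)], labels[c(i0, i1)])
  })
  expect_equal(dl$varA, stats::var(boots), tolerance = 0.15 / dl$varA * dl$varA)
  expect_lt(abs(dl$varA - stats::var(boots)) / dl$varA, 0.15)
})

test_that("ICC matches the two-way ANOVA oracle and handles degeneracy", {
  for (s in 1:10) {
    set.seed(s)
    ratings <- matrix(sample(0:10, 12, replace = TRUE), ncol = 2)
    if (stats::sd(ratings) == 0) next
    expect_equal(icc_agreement(ratings)$icc, aov_icc(ratings),
                 tolerance = 1e-9)
  }

  base <- matrix(c(3, 7, 4, 9, 6, 5), ncol = 1)
  dup <- icc_agreement(cbind(base, base))
  expect_equal(dup$icc, 1)
  expect_equal(dup$category, "excellent")

  # a fixed offset hurts absolute agreement but not consistency
  off <- cbind(base, base + 6)
  abs_icc <- icc_agreement(off)$icc
  consistency <- with(icc_agreement(off),
                      (msr - mse) / (msr + (2 - 1) * mse))
  expect_lt(abs_icc, consistency - 0.3)

  set.seed(44)
  null_icc <- icc_agreement(cbind(rnorm(50), rnorm(50)))$icc
  expect_lt(abs(null_icc), 0.3)

  expect_error(icc_agreement(matrix(1:8, ncol = 2)), "5 subjects")
  expect_error(icc_agreement(matrix(c(1:11, NA), ncol = 2)), "missing")
  flat <- icc_agreement(matrix(5, nrow = 6, ncol = 2))
  expect_true(flat$flagged)
  expect_true(is.na(flat$icc))
})

test_that("ICC confidence interval brackets the point estimate", {
  set.seed(4)
  truth <- rnorm(20, sd = 3)
  ratings <- cbind(truth + rnorm(20, sd = 0.8), truth + rnorm(20, sd = 0.8))
  r <- icc_agreement(ratings)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  expect_gt(r$icc, 0.6)
})

test_that("agreement bands follow the published thresholds", {
  expect_equal(banding(0.936), "excellent")
  expect_equal(banding(0.50), "moderate")
  expect_equal(banding(0.80), "good")
  expect_equal(banding(0.801), "excellent")
  expect_equal(banding(0.40), "poor")
  expect_equal(banding(-0.1), "poor")
  expect_equal(banding(0.61), "good")
})

test_that("feature-wise ICC table mirrors the two-reader protocol", {
  cfg <- shape_config()
  # subjects span sizes and shapes, as real tumors do: without
  # between-subject variance the dimensionless features have no signal
  # for the ICC to detect
  params <- data.frame(radius = c(4, 5, 8, 10, 13, 16),
                       n_lobes = c(14, 3, 12, 5, 8, 10),
                       amplitude = c(0.8, 0, 0.6, 0.3, 0.15, 0.45))
  feats <- lapply(1:6, function(i) {
    pair <- make_phantom_pair(kind = "lobulated", radius = params$radius[i],
                              n_lobes = params$n_lobes[i],
                              amplitude = params$amplitude[i],
                              lobe_width = 0.2, rater_noise = 1, seed = i)
    lapply(pair, function(m) extract_features(m, cfg))
  })
  fa <- do.call(rbind, lapply(feats, `[[`, 1))
  fb <- do.call(rbind, lapply(feats, `[[`, 2))
  fa$subject_id <- fb$subject_id <- sprintf("T%d", 1:6)

  ident <- icc_table(fa, fa)
  expect_equal(ident$icc, rep(1, nrow(ident)), tolerance = 1e-9)
  expect_true(all(ident$category == "excellent"))

  # two noisy readers of six different tumors still agree excellently
  noisy <- icc_table(fa, fb)
  expect_true(all(noisy$icc > 0.8))

  fb_bad <- fb; fb_bad$subject_id[1] <- "zzz"
  expect_error(icc_table(fa, fb_bad), "mismatch")
})

test_that("Fisher-z sample size reproduces the published calculation", {
  expect_identical(sample_size_correlation(0.60, 0.05, 0.80, "one"), 16L)
  expect_identical(sample_size_correlation(0.60, 0.05, 0.80, "two"), 20L)
  expect_identical(sample_size_correlation(0.9999, 0.05, 0.80, "one"), 4L)
  expect_lt(sample_size_correlation(0.9, 0.05, 0.8, "one"), 10)
  expect_error(sample_size_correlation(1e-4, 0.05, 0.8), "exceeds")
  expect_error(sample_size_correlation(0, 0.05, 0.8))
})

test_that("the three-model analysis report is internally consistent", {
  co <- simulate_cohort(seed = 5)
  an <- suppressWarnings(run_shape_analysis(co))
  expect_named(an$models, c("clinical", "shape", "combined"))
  for (m in an$models) {
    expect_equal(nrow(m$loocv), nrow(co))
    expect_true(m$roc$auc >= 0 && m$roc$auc <= 1)
    expect_true(all(m$odds_ratios$adjusted_or ==
                      exp(m$stepwise$fit$coefficients[m$odds_ratios$variable])))
  }
  expect_length(an$comparisons, 3)
  dir <- withr::local_tempdir()
  paths <- write_report(an, dir)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(file.path(dir, "analysis_report.json"))
  expect_equal(rep$models$combined$auc, an$models$combined$roc$auc,
               tolerance = 1e-9)
})
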