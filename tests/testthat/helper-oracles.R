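# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops and closed forms.

# count exposed faces by scanning every voxel's 6 neighbours
brute_exposed_faces <- function(grid) {
  d <- dim(grid)
  total <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (grid[i, j, k] == 0L) next
    for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                    c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
      outside <- any(nb < 1) || nb[1] > d[1] || nb[2] > d[2] || nb[3] > d[3]
      if (outside || grid[nb[1], nb[2], nb[3]] == 0L) total <- total + 1L
    }
  }
  total
}

# AUC by explicit pair counting with ties scored 1/2
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# ICC(A,1) from a stats::aov two-way decomposition
aov_icc <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

dice <- function(a, b) 2 * sum(a$grid & b$grid) / (sum(a$grid) + sum(b$grid))

# deterministic cohort with exactly the given 2x2 composition
counts_cohort <- function(n_enc = 23, n_inv = 30, enc_present = 3,
                          inv_present = 16, variable = "cystic_change") {
  df <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_enc + n_inv)),
    label = rep(c(0L, 1L), c(n_enc, n_inv)))
  df[[variable]] <- c(rep(c(1, 0), c(enc_present, n_enc - enc_present)),
                      rep(c(1, 0), c(inv_present, n_inv - inv_present)))
  as_cohort(df)
}
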