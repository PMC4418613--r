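#!/usr/bin/env Rscript
# The discrimination analysis: univariate screen, the three backward
# stepwise logistic models (clinical+CT / shape / combined), collinearity
# check, leave-one-out cross-validated ROC per model and pairwise DeLong
# comparisons. Reads the cohort written by 01_simulate_cohort.R.

suppressPackageStartupMessages(library(thymoshape))
if (!file.exists("results/cohort.csv"))
  stop("run analysis/01_simulate_cohort.R first")

cohort <- read_cohort("results/cohort.csv")
analysis <- suppressWarnings(run_shape_analysis(cohort))
print(analysis)
write_report(analysis, "results")
cat("\nWrote results/univariate_screen.csv and results/analysis_report.json\n")
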