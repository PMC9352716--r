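#!/usr/bin/env Rscript
# Step 3: for patients only, predict the DNT composite disorientation score
# from each VR navigation variable by standardized linear regression, with
# worst-score imputation for the two wayfinding non-attempters.

suppressPackageStartupMessages(library(navdis))

cohort <- read_cohort_csv("results/cohort.csv")
res <- run_pipeline(cohort, analysis_config())

cat("Standardized regressions of the composite disorientation score:\n")
print(as.data.frame(res$step3_regression[, c("label", "beta_standardized",
                                             "p_value", "significance",
                                             "r_squared", "f_squared",
                                             "n", "n_imputed")]),
      digits = 3, row.names = FALSE)
imp <- grep("imputation", res$log, value = TRUE)
if (length(imp)) cat("\n", paste(imp, collapse = "\n "), "\n", sep = "")
utils::write.csv(res$step3_regression, "results/step3_regression.csv",
                 row.names = FALSE)
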