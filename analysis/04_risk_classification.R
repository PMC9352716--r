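#!/usr/bin/env Rscript
# Step 4: classify patients into high/low spatial-disorientation risk from
# their composite score and test whether the VR variables that predicted the
# composite also predict the risk label (binomial logistic regression).

suppressPackageStartupMessages(library(navdis))

cohort <- read_cohort_csv("results/cohort.csv")
res <- run_pipeline(cohort, analysis_config())

pat <- cohort[cohort$group == "patient" & !is.na(cohort$risk), ]
cat(sprintf("patients: %d high risk, %d low risk\n",
            sum(pat$risk == "high"), sum(pat$risk == "low")))
if (nrow(res$step4_logistic)) {
  cat("\nLogistic risk prediction:\n")
  print(as.data.frame(res$step4_logistic), digits = 3, row.names = FALSE)
} else {
  cat("no VR variable passed step 3 at p < 0.05 on this cohort; ",
      "no logistic model fitted\n", sep = "")
}
utils::write.csv(res$step4_logistic, "results/step4_logistic.csv",
                 row.names = FALSE)
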