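#!/usr/bin/env Rscript
# Step 5 — Monte Carlo cross-validated model comparison.
#
# Compares nested feature sets for predicting any oncogenic alteration vs
# wild-type on the synthetic cohort: clinical-radiological covariates
# alone (CR), CR + largest-lesion cluster, and CR + cluster + dispersion
# range. AUROC is evaluated on the held-out part of 1000 stratified
# Monte Carlo splits shared across feature sets.

library(radstrat)

cohort <- read_cohort("results/cohort")
rep_ <- read.csv("results/patient_representation.csv",
                 stringsAsFactors = FALSE)
clusters <- read.csv("results/cluster_assignments.csv",
                     stringsAsFactors = FALSE)
pat <- merge(merge(cohort$patients, rep_[, c("patient_id",
                                             "dispersion_range")]),
             clusters)
pat$case <- as.integer(pat$molecular_group != "WT")

sets <- list(
  cr = c("sex", "met_pleural"),
  cr_cluster = c("sex", "met_pleural", "cluster_largest"),
  cr_cluster_disp = c("sex", "met_pleural", "cluster_largest",
                      "dispersion_range"))
res <- mccv(pat, "case", sets, n_splits = 1000, test_fraction = 0.3,
            seed = 20260929L)
cmp <- compare_feature_sets(res)
write.csv(cmp$summary, "results/mccv_summary.csv", row.names = FALSE)
write.csv(cmp$differences, "results/mccv_differences.csv",
          row.names = FALSE)

cat("MCCV (1000 splits, 30% held out), any OA vs wild-type:\n")
print(transform(cmp$summary, mean_auroc = round(mean_auroc, 3),
                ci_low = round(ci_low, 3), ci_high = round(ci_high, 3)),
      row.names = FALSE)
cat("\nPaired per-split differences:\n")
print(transform(cmp$differences, mean_diff = round(mean_diff, 3),
                ci_low = round(ci_low, 3), ci_high = round(ci_high, 3)),
      row.names = FALSE)
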