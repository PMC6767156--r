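#!/usr/bin/env Rscript
# Validation arm: in an independent cohort, compare SPM-O against TAPSE,
# TAPSE-F, SFD and SFD-F -- correlation with RVEF, Steiger tests of the
# dependent correlations, covariate-adjusted regression with variance
# partitioning, leave-one-out RVEF prediction, and a Kruskal-Wallis test
# on the absolute errors. Tables land in results/validation.

source(file.path("analysis", "00_common.R"))

co <- make_validation_cohort()
v <- run_validation(co, n_boot = N_BOOT, boot_seed = SEED_BOOT,
                    out_dir = file.path(RESULTS, "validation"))
print(v)

cat("Variance in RVEF explained by each marker (%):\n")
print(round(100 * v$variance_fractions[, "marker"], 1))
cat("Leave-one-out median absolute error (ml):\n")
print(data.frame(marker = v$loo_summary$marker,
                 median_ml = round(v$loo_summary$median_ml, 2)),
      row.names = FALSE)
cat("Tables in", file.path(RESULTS, "validation"), "\n")
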