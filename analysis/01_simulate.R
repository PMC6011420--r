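#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a pregnancy cohort of 1181 women with nine correlated urinary
# phthalate metabolites measured at up to four prenatal visits, applies
# delivery-driven and random visit attrition, censors concentrations at the
# assay detection limits, and draws the nested case-control sample (all
# preterm cases plus 352 random controls with design weights).

library(phthalmix)

out_dir <- "results/cohort"
seed <- 1181

truth <- sim_truth(n_subjects = 1181, seed = seed)
cohort <- simulate_study(truth)
write_cohort(cohort, out_dir)

print(cohort)
cat(sprintf("visit records by visit: %s\n",
            paste(table(cohort$visits$visit), collapse = " / ")))
cat(sprintf("MEHP non-detects: %.2f%%\n", 100 * mean(!cohort$visits$det_mehp)))
cat(sprintf("control design weight: %.4f\n",
            max(cohort$subjects$w[cohort$subjects$preterm == 0])))
cat("cohort written to ", out_dir, "\n")
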