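#!/usr/bin/env Rscript

# Stage 5 - normative statistical layer.
#
# Fits the simple and multiple regressions of the calibrated average SBR and
# of the asymmetry index on age, sex and scan start time; reports Type III
# ANOVA effects; builds the decade-by-sex summary with 95% prediction
# limits; and demonstrates z-scoring of a new subject. Internal-consistency
# figures are recomputed from the bundled published reference summaries.

suppressMessages(library(sbrnorm))

all_scans <- read_cohort("results/cohort.csv")
# the normative database is built on the calibrated uncorrected condition;
# scatter-corrected records carry a residual nonlinearity after affine
# calibration and are kept out of the reference models
cohort <- all_scans[all_scans$condition == "NOACNOSC", ]
cat(sprintf("normative layer fitted on %d calibrated NOACNOSC records\n", nrow(cohort)))

line <- fit_simple_regression(cohort$age, average_sbr(cohort, calibrated = TRUE))
cat(sprintf("pooled age regression: Y = %.4fX + %.3f (r = %.3f, n = %d)\n",
            line$slope, line$intercept, line$r, line$n))

model <- fit_normative_model(cohort, "average_sbr")
print(model)
write_normative_model(model, "results/normative_sbr.json")
ai_model <- fit_normative_model(cohort, "ai")
write_normative_model(ai_model, "results/normative_ai.json")

cat("\nType III ANOVA effects on the average SBR:\n")
print(anova_effects(cohort, "average_sbr"), digits = 3)

dec <- decade_summary(cohort)
write.csv(dec, "results/decade_summary.csv", row.names = FALSE)
cat(sprintf("\ndecade summary written; pooled decline %.1f%% per decade (men %.1f%%, women %.1f%%)\n",
            pct_decline_per_decade(dec, "both"),
            pct_decline_per_decade(dec, "M"),
            pct_decline_per_decade(dec, "F")))

# z-scoring a hypothetical new subject against the fitted model
new_subject <- list(age = 64, sex = "M", scan_start_time = 3.4)
expected <- predict_expected(model, 64, "M", 3.4)
z <- zscore_subject(model, new_subject, observed = 0.6 * expected)
cat(sprintf("\nnew subject (64 y, M): expected SBR %.2f, observed %.2f -> z = %.2f, below lower PI: %s\n",
            z$expected, z$observed, z$z, z$below_lower_pi))

# internal-consistency figures recomputed from the published reference tables
ref_dec <- ref_decade_summary()
ref_cond <- ref_condition_summary()
cat("\npublished-summary consistency checks:\n")
cat(sprintf("  sex difference at 30-39:        %.1f%%\n", pct_sex_difference(ref_dec)))
cat(sprintf("  decline per decade (both):      %.1f%%\n", pct_decline_per_decade(ref_dec, "both")))
cat(sprintf("  decline per decade (men/women): %.1f%% / %.1f%%\n",
            pct_decline_per_decade(ref_dec, "M"), pct_decline_per_decade(ref_dec, "F")))
cat(sprintf("  scan-weighted grand mean:       %.2f\n", scan_weighted_mean(ref_dec, "both")))
cat(sprintf("  calibrated NOACNOSC below ChangACSC: %.0f%%\n",
            pct_condition_difference(ref_cond, "NOACNOSC", "ChangACSC", "calibrated")))
cat(sprintf("  reduction to lower PI at 60-69: %.0f%%\n", pct_pi_reduction(ref_dec)))
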