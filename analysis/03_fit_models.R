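#!/usr/bin/env Rscript
# Stage 3 — stepwise regression model suite and report.
#
# Fits the three stepwise model families on the extracted feature table:
#   1. integral vBMD ~ water-fat-MRI predictors (vertebra level),
#   2. fracture status ~ vBMD + PDFF + T2* (vertebra and patient level),
#   3. fracture status ~ quantitative + all texture features (both levels),
# with forced adjustment covariates (age, sex, and vertebral level where the
# analysis is vertebra-wise), entry threshold p < 0.05, removal at p >= 0.10.
# Writes results/model_report.{json,txt} and prints the paired adjusted-R^2
# comparison that quantifies what texture adds over densitometry alone.

suppressPackageStartupMessages(library(osteotexture))

features <- read_feature_table("results/features.csv")
suite <- run_model_suite(features)
report_model_suite(suite, "results")

print(suite)
gain <- suite$comparison
cat(sprintf("\nTexture features raise adjusted R^2 by %.2f (vertebra level) and %.2f (patient level) over the quantitative-only fracture models.\n",
            gain$r2adj_gain[1], gain$r2adj_gain[2]))
cat("Artifacts: results/model_report.json, results/model_report.txt\n")
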