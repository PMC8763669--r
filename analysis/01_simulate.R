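#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic vertebral cohort.
#
# Generates the default two-group cohort: 26 patients, 7 vertebral levels
# each, fracture prevalence 11/26; the fracture group has lower integral
# vBMD (group means 153.1 vs 218.5 mg/cm^3), higher marrow PDFF, longer T2*
# and a more heterogeneous texture field. Writes per-vertebra NIfTI volumes
# (CT, water, fat, T2*), the shared label mask, the truth table and the
# manifest under results/cohort/.

suppressPackageStartupMessages(library(osteotexture))

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
cfg <- cohort_config(seed = seed)
sim <- generate_cohort(cfg, "results/cohort")

cat(sprintf("Simulated %d vertebrae from %d patients (%d with fracture).\n",
            nrow(sim$manifest), cfg$n_patients,
            length(unique(sim$manifest$patient_id[
              sim$manifest$fracture_status == 1]))))
cat(sprintf("Group truth: vBMD %.1f vs %.1f mg/cm^3, PDFF %.0f vs %.0f %%.\n",
            cfg$mean_vbmd_by_group[1], cfg$mean_vbmd_by_group[2],
            cfg$mean_pdff_by_group[1], cfg$mean_pdff_by_group[2]))
cat("Artifacts: results/cohort/{manifest.csv,truth.csv,config.json,*.nii.gz}\n")
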