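#!/usr/bin/env Rscript

# Step 4: the full six-model comparison (PLSR, DPLSR, OPLS-PLSR, SVR,
# DSVR, OPLS-SVR) end to end: frozen training-set preprocessing, bootstrap
# LV selection for the PLS variants, cross-validated (epsilon, C) grid
# search for the SVR variants, fit on the 16 calibration mixtures, predict
# the 9 test mixtures, rank by test-set RMSEP. Writes the recovery tables
# and a manifest under results/comparison/.

suppressPackageStartupMessages(library(chemocal))

seed <- as.integer(readLines("results/data/seed.txt"))
train_spectra <- read_spectra_csv("results/data/spectra_calibration.csv")
test_spectra <- read_spectra_csv("results/data/spectra_test.csv")
train_design <- read_design_csv("results/data/design_calibration.csv")
test_design <- read_design_csv("results/data/design_test.csv")

config <- comparison_config(bootstrap_seed = seed, cv_seed = seed,
                            outdir = "results/comparison")
report <- run_six_model_comparison(train_spectra, train_design,
                                   test_spectra, test_design, config)
print(report)
message("tables written to results/comparison/ ",
        "(calibration_table.csv, prediction_table.csv, rmsep_by_model.csv, ",
        "manifest.json)")
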