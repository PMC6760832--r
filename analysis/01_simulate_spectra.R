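#!/usr/bin/env Rscript

# Step 1: build the 16-mixture calibration design and the 9-mixture test
# design for pyridostigmine bromide (PR) with impurities A and B, and
# generate Beer-Lambert mixture spectra on the 200-350 nm grid at the
# 0.002 AU noise floor. Writes the designs and spectra under results/data/.

suppressPackageStartupMessages(library(chemocal))

seed <- 20260928L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

train_design <- build_calibration_design()
test_design <- build_test_design()
message("calibration design: ", nrow(train_design$concentrations),
        " mixtures; PR levels ",
        paste(sort(unique(train_design$concentrations[, "PR"])), collapse = "/"),
        " ug/mL")
message("test design: ", nrow(test_design$concentrations), " mixtures")

train_spectra <- generate_mixture_spectra(train_design,
                                          noise = noise_model(0.002, seed = seed))
test_spectra <- generate_mixture_spectra(test_design,
                                         noise = noise_model(0.002, seed = seed + 1L))
message("grid check: ", validate_grid(train_spectra, 200, 350, 1),
        " wavelengths from 200 to 350 nm")

write_design_csv(train_design, file.path(outdir, "design_calibration.csv"))
write_design_csv(test_design, file.path(outdir, "design_test.csv"))
write_spectra_csv(train_spectra, file.path(outdir, "spectra_calibration.csv"))
write_spectra_csv(test_spectra, file.path(outdir, "spectra_test.csv"))
writeLines(as.character(seed), file.path(outdir, "seed.txt"))
message("wrote designs and spectra to ", outdir, " (seed ", seed, ")")
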