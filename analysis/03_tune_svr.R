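#!/usr/bin/env Rscript

# Step 3: grid search for the linear SVR tube width epsilon (0.01-1, step
# 0.01) and penalty C (30-1000, step 10) by 4-fold cross validation on the
# calibration set, for raw, first-derivative and OPLS-filtered spectra.
# Writes one RMSECV grid per variant plus a summary of the optima.

suppressPackageStartupMessages(library(chemocal))

seed <- as.integer(readLines("results/data/seed.txt"))
train_spectra <- read_spectra_csv("results/data/spectra_calibration.csv")
train_design <- read_design_csv("results/data/design_calibration.csv")
y <- design_response(train_design, "PR")

representations <- list(
  SVR = train_spectra,
  DSVR = first_derivative(train_spectra)
)
cm <- fit_center(train_spectra, y)
cen <- apply_center(cm, train_spectra, y)
filt <- fit_opls(cen$X, cen$y, n_ortho = 1)
representations$`OPLS-SVR` <- filt$X_filtered

summary_rows <- list()
for (label in names(representations)) {
  gs <- grid_search_svr(representations[[label]], y, k = 4, seed = seed)
  message(sprintf("%-9s best epsilon %.2f, best C %d (RMSECV %.4f over %d pairs)",
                  label, gs$best_epsilon, as.integer(gs$best_cost),
                  min(gs$grid$rmsecv), nrow(gs$grid)))
  write.csv(gs$grid, sprintf("results/svr_grid_%s.csv", tolower(gsub("-", "_", label))),
            row.names = FALSE, quote = FALSE)
  summary_rows[[label]] <- data.frame(model = label,
                                      best_epsilon = gs$best_epsilon,
                                      best_cost = gs$best_cost,
                                      rmsecv = min(gs$grid$rmsecv))
}
write.csv(do.call(rbind, summary_rows), "results/svr_optima.csv",
          row.names = FALSE, quote = FALSE)
message("wrote results/svr_grid_*.csv and results/svr_optima.csv")
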