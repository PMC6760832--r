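#' Reported reference predictions for the PR system
#'
#' Per-sample predicted concentrations (Found, ug/mL) and percent
#' recoveries of pyridostigmine bromide for the six calibration models
#' (PLSR, DPLSR, OPLS-PLSR, SVR, DSVR, OPLS-SVR), as reported for this
#' system on the 16-mixture calibration set (autoprediction) and the
#' 9-mixture independent test set. The tables are distributed with the
#' package, at their reported precision, so that the footer statistics --
#' mean and SD of the recoveries, RMSEC and RMSEP -- can be recomputed and
#' checked with [summarize_predictions()].
#'
#' @param set `"calibration"` (training-set autoprediction, 16 rows per
#'   model) or `"prediction"` (independent test set, 9 rows per model).
#' @return A data frame with columns `model`, `sample_id`, `taken`,
#'   `found`, `pct_recovery`; `model` is a factor with the six models in
#'   conventional order.
#' @export
reported_reference_predictions <- function(set = c("calibration", "prediction")) {
  set <- match.arg(set)
  file <- system.file("extdata",
                      if (set == "calibration") "reported_predictions_calibration.csv"
                      else "reported_predictions_test.csv",
                      package = "chemocal", mustWork = TRUE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$model <- factor(df$model, levels = reference_model_order())
  stopifnot(!anyNA(df$model))
  df
}

#' Conventional ordering of the six compared models
#'
#' @return Character vector of model labels.
#' @export
reference_model_order <- function() {
  c("PLSR", "DPLSR", "OPLS-PLSR", "SVR", "DSVR", "OPLS-SVR")
}
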