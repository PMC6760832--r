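#' Configuration for the six-model comparison
#'
#' Collects every tunable of the comparison pipeline: which model variants
#' to run, the response analyte, derivative and OPLS settings, bootstrap
#' settings for latent-variable selection, and the (epsilon, C) grid-search
#' settings for the SVR variants. All randomness is driven by the two
#' seeds recorded here.
#'
#' @param models subset of `PLSR`, `DPLSR`, `OPLS-PLSR`, `SVR`, `DSVR`,
#'   `OPLS-SVR` to run (default: all six).
#' @param response analyte quantified (default `"PR"`).
#' @param deriv_method,deriv_window,deriv_polyorder settings passed to
#'   [first_derivative()] for the D-variants.
#' @param n_ortho orthogonal components removed by the OPLS variants.
#' @param n_lv optional fixed LV count; when `NULL` (default) the count is
#'   selected by [bootstrap_select_lv()].
#' @param max_lv,bootstrap_iterations,bootstrap_seed bootstrap settings.
#' @param epsilon_grid,cost_grid,cv_folds,cv_seed grid-search settings.
#' @param outdir optional directory; when set, the run writes
#'   `calibration_table.csv`, `prediction_table.csv`, `rmsep_by_model.csv`
#'   and `manifest.json` there.
#' @return An object of class `comparison_config`.
#' @export
comparison_config <- function(models = reference_model_order(),
                              response = "PR",
                              deriv_method = "finite_difference",
                              deriv_window = 5L,
                              deriv_polyorder = 2L,
                              n_ortho = 1L,
                              n_lv = NULL,
                              max_lv = 10L,
                              bootstrap_iterations = 1000L,
                              bootstrap_seed = 1L,
                              epsilon_grid = seq(0.01, 1, by = 0.01),
                              cost_grid = seq(30, 1000, by = 10),
                              cv_folds = 4L,
                              cv_seed = 1L,
                              outdir = NULL) {
  bad <- setdiff(models, reference_model_order())
  if (length(bad) > 0) {
    stop("unknown model variant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(models) < 1) stop("at least one model variant is required", call. = FALSE)
  if (bootstrap_iterations < 1) stop("bootstrap_iterations must be >= 1", call. = FALSE)
  structure(
    list(models = models, response = response,
         deriv_method = deriv_method, deriv_window = as.integer(deriv_window),
         deriv_polyorder = as.integer(deriv_polyorder),
         n_ortho = as.integer(n_ortho), n_lv = n_lv,
         max_lv = as.integer(max_lv),
         bootstrap_iterations = as.integer(bootstrap_iterations),
         bootstrap_seed = as.integer(bootstrap_seed),
         epsilon_grid = epsilon_grid, cost_grid = cost_grid,
         cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
         outdir = outdir),
    class = "comparison_config"
  )
}

## Build the modeling representation for one variant. Returns the training
## matrix before centering (`rep_tr`/`rep_te`), the frozen centering model,
## the centered-and-filtered matrices actually given to the regressor
## (`Xm_tr`/`Xm_te`), the matrix the bootstrap/grid search should see
## (uncentered for plain/derivative, filtered for OPLS), and the centering
## model to attach to the fitted regressor.
prepare_variant <- function(label, train_spectra, test_spectra, y_tr, config) {
  uses_deriv <- label %in% c("DPLSR", "DSVR")
  uses_opls <- label %in% c("OPLS-PLSR", "OPLS-SVR")
  if (uses_deriv) {
    rep_tr <- first_derivative(train_spectra, method = config$deriv_method,
                               window = config$deriv_window,
                               polyorder = config$deriv_polyorder)
    rep_te <- first_derivative(test_spectra, method = config$deriv_method,
                               window = config$deriv_window,
                               polyorder = config$deriv_polyorder)
  } else {
    rep_tr <- train_spectra
    rep_te <- test_spectra
  }
  cm <- fit_center(rep_tr, y_tr)
  cen <- apply_center(cm, rep_tr, y_tr)
  Xc_tr <- cen$X
  yc_tr <- cen$y
  Xc_te <- apply_center(cm, rep_te)
  if (uses_opls) {
    filt <- fit_opls(Xc_tr, yc_tr, n_ortho = config$n_ortho)
    list(Xm_tr = filt$X_filtered,
         Xm_te = apply_opls(filt, Xc_te),
         X_select = filt$X_filtered,
         yc_tr = yc_tr,
         model_centering = centering_model(NULL, cm$response_mean),
         predict_input_tr = filt$X_filtered,
         predict_input_te = apply_opls(filt, Xc_te),
         filter = filt)
  } else {
    list(Xm_tr = Xc_tr,
         Xm_te = Xc_te,
         X_select = as_absorbance(rep_tr),
         yc_tr = yc_tr,
         model_centering = cm,
         predict_input_tr = rep_tr,
         predict_input_te = rep_te,
         filter = NULL)
  }
}

#' Run the full model comparison
#'
#' For every requested variant: build its spectral representation (raw,
#' first-derivative or OPLS-filtered; all preprocessing parameters are
#' estimated on the training set only and applied frozen to the test set),
#' select its hyperparameters (bootstrap LV count for the PLS variants,
#' cross-validated (epsilon, C) grid search for the SVR variants), fit on
#' the training set, predict both sets, and summarize recoveries and
#' errors. Runs are deterministic for fixed seeds.
#'
#' @param train_spectra,test_spectra [spectra_matrix] objects sharing one
#'   wavelength grid.
#' @param train_design,test_design matching [concentration_design] objects.
#' @param config a [comparison_config].
#' @return An object of class `comparison_report`: per-model list with
#'   `calibration` and `prediction` [summarize_predictions()] reports and
#'   `hyperparameters`, plus `ranking` (model labels by ascending
#'   prediction RMSE) and the `config`.
#' @export
run_six_model_comparison <- function(train_spectra, train_design,
                                     test_spectra, test_design,
                                     config = comparison_config()) {
  stopifnot(inherits(config, "comparison_config"))
  if (!isTRUE(all.equal(train_spectra$wavelengths_nm, test_spectra$wavelengths_nm))) {
    stop("training and test spectra must share one wavelength grid", call. = FALSE)
  }
  y_tr <- design_response(train_design, config$response)
  y_te <- design_response(test_design, config$response)
  results <- list()
  for (label in config$models) {
    results[[label]] <- tryCatch({
      prep <- prepare_variant(label, train_spectra, test_spectra, y_tr, config)
      is_svr <- label %in% c("SVR", "DSVR", "OPLS-SVR")
      if (!is_svr) {
        if (is.null(config$n_lv)) {
          boot <- bootstrap_select_lv(prep$X_select, y_tr,
                                      max_lv = config$max_lv,
                                      n_iterations = config$bootstrap_iterations,
                                      seed = config$bootstrap_seed)
          n_lv <- boot$chosen_lv
        } else {
          boot <- NULL
          n_lv <- as.integer(config$n_lv)
        }
        fit <- fit_pls1(prep$Xm_tr, prep$yc_tr, n_lv,
                        centering = prep$model_centering)
        hyper <- list(n_lv = n_lv, bootstrap = boot)
      } else {
        gs <- grid_search_svr(prep$X_select, y_tr,
                              epsilon_grid = config$epsilon_grid,
                              cost_grid = config$cost_grid,
                              k = config$cv_folds, seed = config$cv_seed)
        fit <- train_linear_svr(prep$Xm_tr, prep$yc_tr,
                                epsilon = gs$best_epsilon, cost = gs$best_cost,
                                centering = prep$model_centering)
        hyper <- list(epsilon = gs$best_epsilon, cost = gs$best_cost,
                      grid_search = gs)
      }
      found_tr <- predict(fit, prep$predict_input_tr)
      found_te <- predict(fit, prep$predict_input_te)
      list(
        calibration = summarize_predictions(y_tr, found_tr, role = "calibration",
                                            sample_ids = train_design$sample_ids),
        prediction = summarize_predictions(y_te, found_te, role = "prediction",
                                           sample_ids = test_design$sample_ids),
        hyperparameters = hyper,
        model = fit
      )
    }, error = function(e) {
      stop("[", label, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- structure(
    list(models = results,
         ranking = NULL,
         config = config),
    class = "comparison_report"
  )
  report$ranking <- rank_models(report)
  if (!is.null(config$outdir)) write_comparison_report(report, config$outdir)
  report
}

#' Rank compared models by prediction error
#'
#' @param report a `comparison_report`.
#' @return Character vector of model labels sorted by ascending prediction
#'   RMSE, ties broken alphabetically.
#' @export
rank_models <- function(report) {
  stopifnot(inherits(report, "comparison_report"), length(report$models) >= 1)
  labels <- names(report$models)
  rmsep <- vapply(report$models, function(m) m$prediction$rmse, numeric(1))
  labels[order(rmsep, labels)]
}

report_long_table <- function(report, which = c("calibration", "prediction")) {
  which <- match.arg(which)
  do.call(rbind, lapply(names(report$models), function(label) {
    ev <- report$models[[label]][[which]]
    data.frame(model = label, sample_id = ev$sample_ids,
               taken = ev$taken, found = ev$found,
               pct_recovery = ev$recovery_percent,
               row.names = NULL)
  }))
}

hyper_string <- function(h) {
  if (!is.null(h$n_lv)) paste0("LV=", h$n_lv)
  else paste0("epsilon=", h$epsilon, ";C=", h$cost)
}

write_comparison_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fmt_num <- function(df) {
    df$found <- sprintf("%.10g", df$found)
    df$pct_recovery <- sprintf("%.10g", df$pct_recovery)
    df
  }
  utils::write.csv(fmt_num(report_long_table(report, "calibration")),
                   file.path(outdir, "calibration_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt_num(report_long_table(report, "prediction")),
                   file.path(outdir, "prediction_table.csv"),
                   row.names = FALSE, quote = FALSE)
  by_model <- data.frame(
    model = names(report$models),
    rmsec = sprintf("%.10g", vapply(report$models, function(m) m$calibration$rmse, numeric(1))),
    rmsep = sprintf("%.10g", vapply(report$models, function(m) m$prediction$rmse, numeric(1))),
    hyperparameters = vapply(report$models, function(m) hyper_string(m$hyperparameters), character(1)),
    row.names = NULL
  )
  utils::write.csv(by_model, file.path(outdir, "rmsep_by_model.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("chemocal")),
    models = names(report$models),
    response = report$config$response,
    n_ortho = report$config$n_ortho,
    bootstrap = list(iterations = report$config$bootstrap_iterations,
                     seed = report$config$bootstrap_seed,
                     max_lv = report$config$max_lv),
    grid_search = list(folds = report$config$cv_folds,
                       seed = report$config$cv_seed,
                       epsilon_range = range(report$config$epsilon_grid),
                       cost_range = range(report$config$cost_grid)),
    chosen = lapply(report$models, function(m) hyper_string(m$hyperparameters)),
    ranking = report$ranking
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report: ", length(x$models), " model(s)\n", sep = "")
  for (label in names(x$models)) {
    m <- x$models[[label]]
    cat(sprintf("  %-10s %-18s RMSEC %.4f  RMSEP %.4f\n", label,
                hyper_string(m$hyperparameters),
                m$calibration$rmse, m$prediction$rmse))
  }
  cat("  ranking (best first): ", paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}
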