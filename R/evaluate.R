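#' Root mean square error
#'
#' sqrt(sum((taken - found)^2) / N). The same formula serves the
#' calibration-set error (RMSEC), the independent-test error (RMSEP) and
#' the pooled cross-validation error (RMSECV).
#'
#' @param taken true concentrations (ug/mL).
#' @param found predicted concentrations (ug/mL).
#' @return A single non-negative value (ug/mL).
#' @export
rmse <- function(taken, found) {
  if (length(taken) != length(found) || length(taken) < 1) {
    stop("shape error: taken and found must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((taken - found)^2))
}

#' Percent recovery
#'
#' Elementwise 100 * found / taken.
#'
#' @param taken true concentrations (ug/mL), strictly positive.
#' @param found predicted concentrations (ug/mL).
#' @return Numeric vector of recoveries (%).
#' @export
recovery_percent <- function(taken, found) {
  if (length(taken) != length(found)) {
    stop("shape error: taken and found must have equal length", call. = FALSE)
  }
  if (any(taken == 0)) stop("division error: taken contains zero", call. = FALSE)
  100 * found / taken
}

## Population-form standard deviation (divisor N).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize predictions as a recovery report
#'
#' Builds the per-sample Taken/Found/%R listing together with the footer
#' statistics: mean recovery, standard deviation of the recoveries and the
#' RMSE. The SD uses divisor N (population form) by default, which is the
#' convention of the reference recovery tables for this system; set
#' `sd_divisor = "n-1"` for the sample form.
#'
#' @param taken true concentrations (ug/mL).
#' @param found predicted concentrations (ug/mL).
#' @param role `"calibration"` (autoprediction of the training set) or
#'   `"prediction"` (independent test set).
#' @param sample_ids optional sample labels.
#' @param sd_divisor `"n"` (default) or `"n-1"`.
#' @param recoveries optional pre-computed percent recoveries to summarize
#'   instead of `100 * found / taken` (used when re-analysing reported
#'   tables whose %R column is printed at fixed precision).
#' @return An object of class `evaluation_report` with fields `sample_ids`,
#'   `taken`, `found`, `recovery_percent`, `mean_recovery`, `sd_recovery`,
#'   `rmse` and `role`.
#' @export
summarize_predictions <- function(taken, found,
                                  role = c("calibration", "prediction"),
                                  sample_ids = NULL,
                                  sd_divisor = c("n", "n-1"),
                                  recoveries = NULL) {
  role <- match.arg(role)
  sd_divisor <- match.arg(sd_divisor)
  if (is.null(recoveries)) {
    recoveries <- recovery_percent(taken, found)
  } else if (length(recoveries) != length(taken)) {
    stop("shape error: recoveries must match taken", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("M", seq_along(taken))
  structure(
    list(sample_ids = sample_ids,
         taken = taken,
         found = found,
         recovery_percent = recoveries,
         mean_recovery = mean(recoveries),
         sd_recovery = if (sd_divisor == "n") sd_pop(recoveries) else stats::sd(recoveries),
         rmse = rmse(taken, found),
         role = role),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("evaluation_report (", x$role, "), ", length(x$taken), " sample(s)\n", sep = "")
  print(data.frame(sample_id = x$sample_ids,
                   taken = x$taken,
                   found = round(x$found, digits),
                   pct_recovery = round(x$recovery_percent, 2)),
        row.names = FALSE)
  cat(sprintf("  Mean (%%) %.2f | S.D %.3f | %s %.4f\n",
              x$mean_recovery, x$sd_recovery,
              if (x$role == "calibration") "RMSEC" else "RMSEP", x$rmse))
  invisible(x)
}

#' Two-sample pooled-variance t test
#'
#' Student's t statistic with pooled variance, its two-tailed p-value and
#' the two-tailed critical value at p = 0.05 on n_a + n_b - 2 degrees of
#' freedom.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`, `critical_value` and a
#'   `degenerate` flag (TRUE when the pooled variance is zero and the means
#'   differ, in which case the statistic is Inf).
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 values", call. = FALSE)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  degenerate <- sp2 == 0
  statistic <- if (!degenerate) {
    delta / sqrt(sp2 * (1 / na + 1 / nb))
  } else if (delta == 0) 0 else Inf * sign(delta)
  list(statistic = statistic,
       df = df,
       p_value = if (is.finite(statistic)) 2 * stats::pt(-abs(statistic), df) else 0,
       critical_value = stats::qt(0.975, df),
       degenerate = degenerate)
}

#' Variance-ratio (F) test
#'
#' Ratio of the larger to the smaller sample variance with the one-tailed
#' critical value at p = 0.05 on the corresponding (n - 1, n - 1) degrees
#' of freedom.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`, `critical_value` and a
#'   `degenerate` flag (TRUE when the smaller variance is zero).
#' @export
f_ratio <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    num <- va; den <- vb; df <- c(na - 1, nb - 1)
  } else {
    num <- vb; den <- va; df <- c(nb - 1, na - 1)
  }
  degenerate <- den == 0
  statistic <- if (!degenerate) num / den else if (num == 0) 1 else Inf
  list(statistic = statistic,
       df = df,
       p_value = if (is.finite(statistic)) stats::pf(statistic, df[1], df[2], lower.tail = FALSE) else 0,
       critical_value = stats::qf(0.95, df[1], df[2]),
       degenerate = degenerate)
}

#' One-way analysis of variance
#'
#' Standard between/within mean-square F over two or more groups, with its
#' p-value and the upper critical value at p = 0.05.
#'
#' @param groups list of numeric vectors (>= 2 groups, each of length >= 2).
#' @return List with `statistic`, `df` (between, within), `p_value`,
#'   `critical_value` and a `degenerate` flag (TRUE when the within-group
#'   variance is zero).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df <- c(length(groups) - 1L, length(values) - length(groups))
  within_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (within_ss == 0) {
    between_ss <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(values))^2,
                             numeric(1)))
    statistic <- if (between_ss == 0) 0 else Inf
    return(list(statistic = statistic, df = df,
                p_value = if (is.finite(statistic)) 1 else 0,
                critical_value = stats::qf(0.95, df[1], df[2]),
                degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df = df,
       p_value = unname(fit$p.value),
       critical_value = stats::qf(0.95, df[1], df[2]),
       degenerate = FALSE)
}
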