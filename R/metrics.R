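# SAMPL-style evaluation: signed-error statistics, correlations,
# bootstrap uncertainties and ranked error profiles.

#' Validate a prediction set
#'
#' A prediction set pairs predicted and experimental log D values per
#' solute. Solute ids must be unique; `pred_uncertainty` is optional.
#'
#' @param data Data frame with `solute_id`, `predicted`, `experimental`
#'   and optionally `pred_uncertainty`.
#' @return The validated tibble.
#' @export
as_prediction_set <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("solute_id", "predicted", "experimental")
  if (!all(need %in% names(data))) {
    .abort(paste("Prediction set missing columns:",
                 paste(setdiff(need, names(data)), collapse = ", ")),
           "dielbal_format_error")
  }
  if (nrow(data) == 0L) {
    .abort("Prediction set is empty.", "dielbal_value_error")
  }
  if (anyDuplicated(data$solute_id)) {
    .abort("Duplicate solute_id in prediction set.", "dielbal_value_error")
  }
  data
}

#' Signed, absolute and root-mean-square error
#'
#' @param ps A prediction set (see [as_prediction_set()]).
#' @return One-row tibble `mse` (mean signed error, predicted minus
#'   experimental), `aue` (mean absolute error), `rmse`. Always
#'   `rmse >= aue >= |mse|`.
#' @examples
#' error_stats(data.frame(solute_id = 1:3, predicted = c(1, -1, 2),
#'                        experimental = 0))
#' @export
error_stats <- function(ps) {
  ps <- as_prediction_set(ps)
  e <- ps$predicted - ps$experimental
  tibble::tibble(mse = mean(e), aue = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

.warn_undefined <- function(what) {
  rlang::warn(sprintf("%s is undefined for this prediction set (zero variance).", what),
              class = "dielbal_undefined_correlation")
  NA_real_
}

#' Pearson correlation of predictions with experiment
#'
#' @param ps A prediction set with >= 2 entries.
#' @return Sample Pearson R, or `NA` with a `dielbal_undefined_correlation`
#'   warning when either column has zero variance (e.g. the null
#'   baseline) -- an explicit undefined signal, never a fake 0.
#' @export
pearson_r <- function(ps) {
  ps <- as_prediction_set(ps)
  if (nrow(ps) < 2L) .abort("Need >= 2 entries for a correlation.", "dielbal_value_error")
  if (stats::sd(ps$predicted) == 0 || stats::sd(ps$experimental) == 0) {
    return(.warn_undefined("Pearson correlation"))
  }
  stats::cor(ps$predicted, ps$experimental)
}

#' Kendall rank correlation (tau-b) of predictions with experiment
#'
#' Tie-corrected tau-b over the (predicted, experimental) pairs.
#'
#' @param ps A prediction set with >= 2 entries.
#' @return tau-b, or `NA` with a `dielbal_undefined_correlation` warning
#'   when either column is entirely tied.
#' @export
kendall_tau <- function(ps) {
  ps <- as_prediction_set(ps)
  if (nrow(ps) < 2L) .abort("Need >= 2 entries for a correlation.", "dielbal_value_error")
  if (length(unique(ps$predicted)) == 1L || length(unique(ps$experimental)) == 1L) {
    return(.warn_undefined("Kendall's tau"))
  }
  stats::cor(ps$predicted, ps$experimental, method = "kendall")
}

# raw kernels used on bootstrap resamples (which repeat solutes, so the
# prediction-set validation must not run on them)
.metric_fun <- function(metric) {
  switch(metric,
    mse = function(ps) mean(ps$predicted - ps$experimental),
    aue = function(ps) mean(abs(ps$predicted - ps$experimental)),
    rmse = function(ps) sqrt(mean((ps$predicted - ps$experimental)^2)),
    pearson_r = function(ps) {
      if (stats::sd(ps$predicted) == 0 || stats::sd(ps$experimental) == 0) {
        return(NA_real_)
      }
      stats::cor(ps$predicted, ps$experimental)
    },
    kendall_tau = function(ps) {
      if (length(unique(ps$predicted)) == 1L ||
          length(unique(ps$experimental)) == 1L) {
        return(NA_real_)
      }
      stats::cor(ps$predicted, ps$experimental, method = "kendall")
    },
    .abort(sprintf("Unknown metric '%s'; choose one of mse, aue, rmse, pearson_r, kendall_tau.",
                   metric), "dielbal_value_error")
  )
}

#' Bootstrap uncertainty of an evaluation metric
#'
#' Case resampling of solutes with replacement: the prediction set's
#' rows are resampled `n_boot` times and the metric recomputed on each
#' resample. The spread (standard deviation) across resamples is the
#' reported uncertainty. Fully determined by `seed`.
#'
#' @param ps A prediction set.
#' @param metric One of `"mse"`, `"aue"`, `"rmse"`, `"pearson_r"`,
#'   `"kendall_tau"`.
#' @param n_boot Number of resamples (>= 100; default 10000).
#' @param seed Integer seed.
#' @return Named list `mean`, `stddev` of the metric over resamples.
#' @examples
#' ps <- gen_prediction_set(prediction_set_spec(n_solutes = 20, seed = 7))
#' bootstrap_metric(ps, "mse", n_boot = 200, seed = 1)
#' @export
bootstrap_metric <- function(ps, metric = "mse", n_boot = 10000L, seed = 1L) {
  ps <- as_prediction_set(ps)
  if (n_boot < 100L) .abort("`n_boot` must be >= 100.", "dielbal_value_error")
  f <- .metric_fun(metric)
  n <- nrow(ps)
  vals <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    f(ps[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, 0))
  list(mean = mean(vals, na.rm = TRUE), stddev = stats::sd(vals, na.rm = TRUE))
}

#' Ranked signed-error profile
#'
#' Entries ordered by ascending experimental log D (ties broken by
#' solute_id), with each solute's signed error. This is the ordering of
#' the signed-error bar charts used to expose an exaggerated prediction
#' slope: errors run from predominantly negative to predominantly
#' positive when predictions over-respond to experiment.
#'
#' @param ps A prediction set.
#' @return Tibble `solute_id`, `experimental`, `signed_error`, sorted.
#' @export
error_profile <- function(ps) {
  ps <- as_prediction_set(ps)
  ps |>
    dplyr::mutate(signed_error = .data$predicted - .data$experimental) |>
    dplyr::arrange(.data$experimental, .data$solute_id) |>
    dplyr::select("solute_id", "experimental", "signed_error")
}

#' Dynamic range of a set of log D values
#'
#' @param values Numeric vector (>= 1 value).
#' @return `max(values) - min(values)`.
#' @examples
#' dynamic_range(c(-4, 3)) # 7
#' @export
dynamic_range <- function(values) {
  if (length(values) < 1L) .abort("Need at least one value.", "dielbal_value_error")
  max(values) - min(values)
}

#' Full evaluation of a prediction set
#'
#' Computes every reported statistic at once: signed/absolute/RMS error,
#' Pearson R, Kendall tau-b, the OLS regression of predicted on
#' experimental, both dynamic ranges, and bootstrap uncertainties for
#' the requested metrics.
#'
#' @param ps A prediction set.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param bootstrap_metrics Character vector of metrics to bootstrap
#'   (default `"mse"`, `"aue"`, `"rmse"`).
#' @return A `metric_report` object; see [tidy.metric_report()],
#'   [glance.metric_report()], [autoplot.metric_report()].
#' @examples
#' ps <- gen_prediction_set(prediction_set_spec(n_solutes = 30, seed = 5))
#' rep <- evaluate(ps, n_boot = 200, seed = 1)
#' glance(rep)
#' @export
evaluate <- function(ps, n_boot = 10000L, seed = 1L,
                     bootstrap_metrics = c("mse", "aue", "rmse")) {
  ps <- as_prediction_set(ps)
  es <- error_stats(ps)
  r <- suppressWarnings(pearson_r(ps))
  tau <- suppressWarnings(kendall_tau(ps))
  fit <- stats::lm(predicted ~ experimental, data = ps)
  boot <- purrr::map(rlang::set_names(bootstrap_metrics), function(m) {
    bootstrap_metric(ps, m, n_boot = n_boot, seed = seed)
  })
  structure(list(
    n = nrow(ps),
    mse = es$mse, aue = es$aue, rmse = es$rmse,
    pearson_r = r, kendall_tau = tau,
    ols_slope = unname(stats::coef(fit)[2]),
    ols_intercept = unname(stats::coef(fit)[1]),
    dynamic_range_pred = dynamic_range(ps$predicted),
    dynamic_range_exp = dynamic_range(ps$experimental),
    bootstrap = boot,
    prediction_set = ps,
    n_boot = n_boot, seed = seed
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d solutes\n", x$n))
  cat(sprintf("  MSE %.3f  AUE %.3f  RMSE %.3f\n", x$mse, x$aue, x$rmse))
  cat(sprintf("  Pearson R %s  Kendall tau %s\n",
              format(x$pearson_r, digits = 3), format(x$kendall_tau, digits = 3)))
  cat(sprintf("  OLS: predicted = %.3f * experimental %+.3f\n",
              x$ols_slope, x$ols_intercept))
  cat(sprintf("  dynamic range: predictions %.2f, experiment %.2f\n",
              x$dynamic_range_pred, x$dynamic_range_exp))
  for (m in names(x$bootstrap)) {
    cat(sprintf("  bootstrap %s: %.3f +/- %.3f (%d resamples)\n",
                m, x$bootstrap[[m]]$mean, x$bootstrap[[m]]$stddev, x$n_boot))
  }
  invisible(x)
}

#' Tidy a metric report into a long tibble
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Tibble `metric`, `value`, `boot_mean`, `boot_stddev` (the
#'   bootstrap columns are `NA` for metrics not bootstrapped).
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  metrics <- c("mse", "aue", "rmse", "pearson_r", "kendall_tau",
               "ols_slope", "ols_intercept", "dynamic_range_pred",
               "dynamic_range_exp")
  tibble::tibble(
    metric = metrics,
    value = vapply(metrics, function(m) x[[m]], 0, USE.NAMES = FALSE),
    boot_mean = vapply(metrics, function(m)
      if (m %in% names(x$bootstrap)) x$bootstrap[[m]]$mean else NA_real_,
      0, USE.NAMES = FALSE),
    boot_stddev = vapply(metrics, function(m)
      if (m %in% names(x$bootstrap)) x$bootstrap[[m]]$stddev else NA_real_,
      0, USE.NAMES = FALSE)
  )
}

#' One-row summary of a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return One-row tibble of all scalar statistics.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, mse = x$mse, aue = x$aue, rmse = x$rmse,
    pearson_r = x$pearson_r, kendall_tau = x$kendall_tau,
    ols_slope = x$ols_slope, ols_intercept = x$ols_intercept,
    dynamic_range_pred = x$dynamic_range_pred,
    dynamic_range_exp = x$dynamic_range_exp
  )
}

#' Correlation plot for a metric report
#'
#' Predicted versus experimental log D with the identity line (dashed)
#' and the OLS fit (solid); a slope above 1 is the "exaggerated
#' prediction" signature.
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  ps <- object$prediction_set
  ggplot2::ggplot(ps, ggplot2::aes(x = .data$experimental, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$ols_slope,
                         intercept = object$ols_intercept, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "experimental log D", y = "predicted log D",
                  title = sprintf("R = %.2f, tau = %.2f, RMSE = %.2f",
                                  object$pearson_r, object$kendall_tau,
                                  object$rmse)) +
    ggplot2::theme_minimal()
}

#' Signed-error bar chart ordered by experimental log D
#'
#' @param ps A prediction set.
#' @return A ggplot object: signed-error bars with the experimental
#'   values overlaid as a line, ordered by increasing experimental
#'   log D.
#' @export
plot_error_profile <- function(ps) {
  prof <- error_profile(ps)
  prof$rank <- seq_len(nrow(prof))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$signed_error), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$experimental), colour = "red") +
    ggplot2::labs(x = "solutes ordered by experimental log D",
                  y = "signed error / experimental log D") +
    ggplot2::theme_minimal()
}
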