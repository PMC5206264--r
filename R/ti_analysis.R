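# Thermodynamic integration: trapezoid assembly of solvation free
# energies from per-lambda-window <dH/dlambda> means, with the two-leg
# (nonpolar grow + polar charge-on) decomposition.

#' Construct a lambda schedule
#'
#' @param values Strictly increasing numeric vector in \[0, 1\] starting
#'   at 0 and ending at 1, length >= 2.
#' @param leg `"nonpolar"` or `"polar"`.
#' @return A `lambda_schedule` object.
#' @seealso [default_schedule()]
#' @export
lambda_schedule <- function(values, leg = c("nonpolar", "polar")) {
  leg <- match.arg(leg)
  values <- as.numeric(values)
  if (length(values) < 2L || any(diff(values) <= 0) ||
      values[1] != 0 || values[length(values)] != 1) {
    .abort("Lambda values must be strictly increasing from 0.0 to 1.0 with length >= 2.",
           "dielbal_value_error")
  }
  structure(list(leg = leg, values = values), class = "lambda_schedule")
}

#' Default lambda schedules for the two alchemical legs
#'
#' The nonpolar (uncharged-solute growth) leg uses the 17-point schedule
#' 0.0, 0.05, 0.1, then 0.1 spacing to 0.5, then 0.05 spacing to 1.0;
#' the polar (charge-switching) leg uses 6 evenly spaced points from 0.0
#' to 1.0 (spacing 0.2).
#'
#' @param leg `"nonpolar"` or `"polar"`.
#' @return A `lambda_schedule`.
#' @examples
#' default_schedule("nonpolar")$values
#' default_schedule("polar")$values
#' @export
default_schedule <- function(leg = c("nonpolar", "polar")) {
  leg <- match.arg(leg)
  if (leg == "nonpolar") {
    lambda_schedule(c(0.0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.55, 0.6, 0.65,
                      0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1.0), "nonpolar")
  } else {
    lambda_schedule(seq(0, 1, length.out = 6), "polar")
  }
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %s leg, %d windows: %s\n", x$leg,
              length(x$values), paste(format(x$values), collapse = " ")))
  invisible(x)
}

#' Block-averaged mean and standard error of one TI window
#'
#' MD gradient samples are serially correlated, so the naive standard
#' error of the mean underestimates the true uncertainty. The samples
#' are split into `n_blocks` contiguous blocks; the window mean is the
#' arithmetic mean of all samples and the standard error is
#' `sd(block means) / sqrt(n_blocks)`.
#'
#' @param samples Numeric vector of dH/dlambda samples, kJ/mol.
#' @param n_blocks Number of contiguous blocks (>= 2, <= length(samples)).
#' @return Named list `mean`, `stderr` (kJ/mol).
#' @examples
#' window_mean(c(1, 3), n_blocks = 2) # mean 2, stderr 1
#' @export
window_mean <- function(samples, n_blocks = 5L) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n_blocks < 2L || n < n_blocks) {
    .abort(sprintf("Need at least n_blocks = %d samples (got %d) with n_blocks >= 2.",
                   n_blocks, n), "dielbal_value_error")
  }
  blk <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  bm <- vapply(split(samples, blk), mean, 0)
  list(mean = mean(samples), stderr = stats::sd(bm) / sqrt(n_blocks))
}

.trapezoid_weights <- function(lambda) {
  n <- length(lambda)
  w <- numeric(n)
  d <- diff(lambda)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Integrate per-window gradient means over a lambda schedule
#'
#' Composite trapezoid rule over the schedule's (possibly uneven) nodes:
#' `dG = sum_i w_i * mean_i`. Window standard errors, when supplied,
#' propagate through the trapezoid weights in quadrature:
#' `u = sqrt(sum_i (w_i * stderr_i)^2)`.
#'
#' @param schedule A `lambda_schedule`.
#' @param means Numeric vector of per-window mean dH/dlambda (kJ/mol),
#'   one per schedule point.
#' @param stderrs Optional numeric vector of per-window standard errors.
#' @return Named list `dG`, `uncertainty` (kJ/mol; uncertainty 0 when no
#'   stderrs given).
#' @examples
#' s <- default_schedule("polar")
#' integrate_ti(s, 12 * s$values)$dG # linear integrand: exactly 6
#' @export
integrate_ti <- function(schedule, means, stderrs = NULL) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  lam <- schedule$values
  if (length(means) != length(lam)) {
    .abort(sprintf("Schedule has %d windows but %d means were supplied.",
                   length(lam), length(means)), "dielbal_value_error")
  }
  w <- .trapezoid_weights(lam)
  dG <- sum(w * means)
  unc <- 0
  if (!is.null(stderrs)) {
    if (length(stderrs) != length(lam)) {
      .abort("stderrs length must match the schedule.", "dielbal_value_error")
    }
    unc <- sqrt(sum((w * stderrs)^2))
  }
  list(dG = dG, uncertainty = unc)
}

#' Build per-window TI data from a long or summary table
#'
#' Accepts either long-form samples (`lambda`, `sample`) or precomputed
#' summaries (`lambda`, `mean`, `stderr`) and reduces them to one mean
#' and standard error per window, block-averaging long-form samples.
#'
#' @param data Data frame in one of the two layouts.
#' @param n_blocks Blocks for [window_mean()] on long-form input.
#' @param discard_fraction Leading fraction of each window's samples to
#'   drop as equilibration (default 0; inputs are assumed
#'   post-equilibration).
#' @return Tibble with columns `lambda`, `mean`, `stderr`, `n_samples`.
#' @export
ti_windows <- function(data, n_blocks = 5L, discard_fraction = 0) {
  data <- tibble::as_tibble(data)
  if (all(c("lambda", "mean") %in% names(data))) {
    out <- tibble::tibble(lambda = as.numeric(data$lambda),
                          mean = as.numeric(data$mean),
                          stderr = if ("stderr" %in% names(data))
                            as.numeric(data$stderr) else 0,
                          n_samples = NA_integer_)
    return(dplyr::arrange(out, .data$lambda))
  }
  if (!all(c("lambda", "sample") %in% names(data))) {
    .abort("Expected columns (lambda, sample) or (lambda, mean[, stderr]).",
           "dielbal_format_error")
  }
  if (discard_fraction < 0 || discard_fraction >= 1) {
    .abort("`discard_fraction` must be in [0, 1).", "dielbal_value_error")
  }
  data |>
    dplyr::group_by(lambda = as.numeric(.data$lambda)) |>
    dplyr::summarise(res = {
      s <- as.numeric(.data$sample)
      s <- s[(floor(discard_fraction * length(s)) + 1L):length(s)]
      wm <- window_mean(s, n_blocks)
      tibble::tibble(mean = wm$mean, stderr = wm$stderr,
                     n_samples = length(s))
    }, .groups = "drop") |>
    tidyr::unnest("res") |>
    dplyr::arrange(.data$lambda)
}

.match_schedule <- function(windows, leg) {
  sched <- lambda_schedule(sort(unique(windows$lambda)), leg)
  sched
}

#' Solvation free energy from two alchemical legs
#'
#' Assembles the total solvation free energy of one solute in one
#' solvent as the sum of two separated alchemical processes: growing the
#' uncharged solute (nonpolar leg, `dG_np`) and switching on its charges
#' (polar leg, `dG_pol`). Each leg is integrated with [integrate_ti()]
#' over the lambda values present in its table; leg uncertainties
#' combine in quadrature.
#'
#' @param np_windows,pol_windows Data frames accepted by [ti_windows()]
#'   for the nonpolar and polar legs.
#' @param solute_id,solvent_id Identifiers recorded in the result.
#' @param n_blocks Blocks for long-form window reduction.
#' @return One-row tibble: `solute_id`, `solvent_id`, `dG_np`, `dG_pol`,
#'   `dG_solv` (their exact sum), `uncertainty` (all kJ/mol).
#' @examples
#' s <- default_schedule("polar")
#' pol <- data.frame(lambda = s$values, mean = -12 * s$values, stderr = 0.1)
#' np <- data.frame(lambda = default_schedule("nonpolar")$values, mean = 2, stderr = 0.1)
#' solvation_free_energy(np, pol, "toy", "water")
#' @export
solvation_free_energy <- function(np_windows, pol_windows,
                                  solute_id = "solute", solvent_id = "solvent",
                                  n_blocks = 5L) {
  npw <- ti_windows(np_windows, n_blocks)
  pw <- ti_windows(pol_windows, n_blocks)
  np <- integrate_ti(.match_schedule(npw, "nonpolar"), npw$mean, npw$stderr)
  pol <- integrate_ti(.match_schedule(pw, "polar"), pw$mean, pw$stderr)
  tibble::tibble(
    solute_id = solute_id, solvent_id = solvent_id,
    dG_np = np$dG, dG_pol = pol$dG, dG_solv = np$dG + pol$dG,
    uncertainty = sqrt(np$uncertainty^2 + pol$uncertainty^2)
  )
}
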