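# Synthetic inputs with known ground truth: toy topologies, analytic
# TI gradient profiles, prediction sets with controlled bias/slope/noise,
# and dipole series generated for a chosen dielectric constant. Every
# generator is a pure function of its seed.

#' Generate a random toy molecule topology
#'
#' Charges are drawn uniformly on (-0.5, 0.5) and then shifted so their
#' sum equals `net_charge` exactly; Lennard-Jones sigma is uniform on
#' \[0.05, 0.4\] nm, epsilon on \[0.1, 1.0\] kJ/mol, mass on \[1, 35\]
#' amu. Each atom gets its own atom type so per-atom parameters survive
#' a write/read round trip.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param net_charge Target net charge, e.
#' @param seed Integer seed; same seed, identical topology.
#' @return A `molecule_topology`.
#' @examples
#' sum(gen_topology(10, net_charge = 0, seed = 1)$atoms$charge) # 0
#' @export
gen_topology <- function(n_atoms, net_charge = 0, seed = 1L) {
  stopifnot(n_atoms >= 1)
  withr::with_seed(seed, {
    q <- stats::runif(n_atoms, -0.5, 0.5)
    q <- q - mean(q) + net_charge / n_atoms
    atoms <- tibble::tibble(
      index = seq_len(n_atoms),
      type_name = sprintf("ty%02d", seq_len(n_atoms)),
      residue = "MOL",
      atom_name = sprintf("A%d", seq_len(n_atoms)),
      charge = q,
      sigma = stats::runif(n_atoms, 0.05, 0.4),
      epsilon = stats::runif(n_atoms, 0.1, 1.0),
      mass = stats::runif(n_atoms, 1, 35)
    )
    new_molecule_topology(sprintf("SYN%d", seed), atoms)
  })
}

#' Specify an analytic TI gradient profile
#'
#' The true integrand `<dH/dlambda>(lambda)` is the polynomial
#' `sum(coefficients[k] * lambda^(k-1))`; its exact integral over
#' \[0, 1\] is `sum(coefficients[k] / k)`, the ground truth against
#' which the trapezoid assembly is checked.
#'
#' @param coefficients Polynomial coefficients, constant term first,
#'   kJ/mol.
#' @param noise_sigma Gaussian noise added per sample, kJ/mol (>= 0).
#' @param samples_per_window Samples generated per lambda window (>= 1).
#' @param seed Integer seed.
#' @return A `ti_profile_spec` list with the derived `true_dG`.
#' @export
ti_profile_spec <- function(coefficients, noise_sigma = 0,
                            samples_per_window = 100L, seed = 1L) {
  stopifnot(length(coefficients) >= 1, noise_sigma >= 0, samples_per_window >= 1)
  structure(list(
    coefficients = as.numeric(coefficients),
    noise_sigma = noise_sigma,
    samples_per_window = as.integer(samples_per_window),
    seed = as.integer(seed),
    true_dG = sum(coefficients / seq_along(coefficients))
  ), class = "ti_profile_spec")
}

# Horner evaluation, constant term first
.polyval <- function(coef, x) {
  out <- rep(0, length(x))
  for (ck in rev(coef)) out <- out * x + ck
  out
}

#' Generate per-window TI samples from an analytic profile
#'
#' @param spec A [ti_profile_spec()].
#' @param schedule A `lambda_schedule` (default the 17-point nonpolar
#'   schedule).
#' @return List: `windows`, a long tibble (`lambda`, `sample`) with
#'   `spec$samples_per_window` noisy samples of the polynomial at each
#'   schedule point, and `true_dG`, the exact polynomial integral over
#'   \[0, 1\].
#' @examples
#' gw <- gen_ti_windows(ti_profile_spec(c(0, 12)), default_schedule("polar"))
#' gw$true_dG # 6
#' @export
gen_ti_windows <- function(spec, schedule = default_schedule("nonpolar")) {
  stopifnot(inherits(spec, "ti_profile_spec"), inherits(schedule, "lambda_schedule"))
  truth <- .polyval(spec$coefficients, schedule$values)
  windows <- withr::with_seed(spec$seed, {
    purrr::map2_dfr(schedule$values, truth, function(lam, mu) {
      tibble::tibble(lambda = lam,
                     sample = mu + stats::rnorm(spec$samples_per_window,
                                                0, spec$noise_sigma))
    })
  })
  list(windows = windows, true_dG = spec$true_dG)
}

#' Specify a synthetic prediction set
#'
#' Emulates a blind-challenge evaluation set: experimental log D values
#' uniform over the measured range (default \[-4, 3\], the experimental
#' spread of the 53-compound water/cyclohexane set), predictions built
#' as `bias + slope * experimental + Gaussian(0, noise_sigma)` so a
#' known systematic bias and exaggerated slope can be dialed in.
#'
#' @param n_solutes Number of solutes (>= 2; default 53).
#' @param exp_low,exp_high Experimental range, log D units.
#' @param slope Dimensionless prediction slope (default 1).
#' @param bias Systematic offset, log D units (default 0).
#' @param noise_sigma Gaussian prediction noise, log D units.
#' @param seed Integer seed.
#' @return A `prediction_set_spec` list.
#' @export
prediction_set_spec <- function(n_solutes = 53L, exp_low = -4, exp_high = 3,
                                slope = 1, bias = 0, noise_sigma = 0, seed = 1L) {
  stopifnot(n_solutes >= 2, exp_high > exp_low, noise_sigma >= 0)
  structure(list(n_solutes = as.integer(n_solutes), exp_low = exp_low,
                 exp_high = exp_high, slope = slope, bias = bias,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "prediction_set_spec")
}

#' Generate a synthetic prediction set
#'
#' @param spec A [prediction_set_spec()].
#' @return A prediction-set tibble (`solute_id`, `predicted`,
#'   `experimental`), deterministic in `spec$seed`.
#' @examples
#' ps <- gen_prediction_set(prediction_set_spec(n_solutes = 10, bias = 4.6, seed = 2))
#' error_stats(ps)$mse # 4.6
#' @export
gen_prediction_set <- function(spec) {
  stopifnot(inherits(spec, "prediction_set_spec"))
  withr::with_seed(spec$seed, {
    expv <- stats::runif(spec$n_solutes, spec$exp_low, spec$exp_high)
    pred <- spec$bias + spec$slope * expv +
      stats::rnorm(spec$n_solutes, 0, spec$noise_sigma)
    tibble::tibble(solute_id = sprintf("S%03d", seq_len(spec$n_solutes)),
                   predicted = pred, experimental = expv)
  })
}

#' Generate a dipole series with a known dielectric constant
#'
#' Draws isotropic Gaussian total-dipole components whose per-axis
#' variance is `(target_epsilon - 1) * eps0 * V * R * T` (e nm units),
#' inverting the fluctuation formula so [epsilon_from_dipoles()]
#' recovers `target_epsilon` in expectation. `target_epsilon = 1` gives
#' a zero-variance (constant) series.
#'
#' @param target_epsilon Desired static dielectric constant (>= 1).
#' @param volume Box volume, nm^3.
#' @param temperature Kelvin.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @return A `dipole_series`.
#' @examples
#' ds <- gen_dipole_series(78.4, volume = 30, temperature = 298.15,
#'                         n_frames = 5000, seed = 3)
#' epsilon_from_dipoles(ds)
#' @export
gen_dipole_series <- function(target_epsilon, volume = 30, temperature = 298.15,
                              n_frames = 1e5, seed = 1L) {
  if (target_epsilon < 1) {
    .abort("`target_epsilon` must be >= 1.", "dielbal_value_error")
  }
  kT <- .const$R_kJmol * temperature
  v <- (target_epsilon - 1) * .const$eps0 * volume * kT
  m <- withr::with_seed(seed,
    matrix(stats::rnorm(3 * n_frames, 0, sqrt(v)), ncol = 3,
           dimnames = list(NULL, c("Mx", "My", "Mz"))))
  dipole_series(m, volume, temperature)
}
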