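# Static dielectric constant from total-dipole fluctuations, the
# vaporization-enthalpy estimator, and the solvent-model registry that
# defines "dielectric balance".

#' Construct a total-dipole time series
#'
#' @param dipoles Matrix or data frame with columns `Mx`, `My`, `Mz`:
#'   the simulation box's total dipole per frame, in e nm.
#' @param volume Box volume, nm^3.
#' @param temperature Kelvin.
#' @return A `dipole_series` object.
#' @export
dipole_series <- function(dipoles, volume, temperature) {
  m <- as.matrix(as.data.frame(dipoles)[, c("Mx", "My", "Mz")])
  if (nrow(m) < 2L) .abort("Need at least 2 dipole frames.", "dielbal_value_error")
  if (volume <= 0) .abort("`volume` must be positive (nm^3).", "dielbal_value_error")
  if (temperature <= 0) .abort("`temperature` must be positive (K).", "dielbal_value_error")
  structure(list(dipoles = m, volume = volume, temperature = temperature),
            class = "dipole_series")
}

#' Static dielectric constant from dipole fluctuations
#'
#' Conducting ("tin-foil") boundary fluctuation formula, consistent with
#' Ewald electrostatics:
#' \deqn{\epsilon(0) = 1 + \frac{\langle M^2\rangle - \langle M\rangle^2}
#'   {3 \epsilon_0 V k_B T}}
#' with the total dipole M in e nm, V in nm^3 and \eqn{k_B T} as RT in
#' kJ/mol, so \eqn{\epsilon_0} is expressed in e^2 mol kJ^-1 nm^-1 (see
#' [dielbal_constants()]). A fluctuation-free series returns exactly 1;
#' the estimate is always >= 1.
#'
#' @param ds A [dipole_series()].
#' @return The estimated static dielectric constant (dimensionless).
#' @examples
#' ds <- gen_dipole_series(2.0, volume = 30, temperature = 298.15,
#'                         n_frames = 20000, seed = 1)
#' epsilon_from_dipoles(ds)
#' @export
epsilon_from_dipoles <- function(ds) {
  stopifnot(inherits(ds, "dipole_series"))
  m <- ds$dipoles
  n <- nrow(m)
  mu <- colMeans(m)
  # population (1/N) fluctuation, the ensemble-average convention
  fluct <- sum(colMeans(m^2) - mu^2)
  kT <- .const$R_kJmol * ds$temperature
  1 + fluct / (3 * .const$eps0 * ds$volume * kT)
}

#' Molar enthalpy of vaporization from mean potential energies
#'
#' `dHvap = U_gas - U_liq + R T`, with per-molecule (molar) potential
#' energies in kJ/mol. One of the calibration targets (alongside density
#' and the static dielectric constant) used when tuning a
#' dielectric-corrected solvent model.
#'
#' @param u_liq_per_mol Mean liquid-phase potential energy per mole of
#'   molecules, kJ/mol.
#' @param u_gas Mean gas-phase (isolated molecule) potential energy,
#'   kJ/mol.
#' @param temperature Kelvin.
#' @return dHvap in kJ/mol.
#' @examples
#' hvap_from_energies(-30, 0, 298.15) # 32.479
#' @export
hvap_from_energies <- function(u_liq_per_mol, u_gas, temperature = 298.15) {
  if (any(temperature <= 0)) {
    .abort("`temperature` must be positive (K).", "dielbal_value_error")
  }
  u_gas - u_liq_per_mol + .const$R_kJmol * temperature
}

#' Registry of solvent models and their dielectric targets
#'
#' The fixed solvent models of the dielectric-balancing workflow with
#' the static dielectric constants that motivate it: TIP3P water
#' overshoots at epsilon(0) = 98 and plain united-atom cyclohexane is
#' entirely nonpolar (epsilon(0) = 1), while the experimental values are
#' 78.4 and 2.0. The dielectric-corrected models H2O-DC and CYH-DC
#' target the experimental values.
#'
#' @return Tibble `name`, `kind` (aqueous/nonpolar), `epsilon_model`
#'   (known value for the model, NA if defined by its target),
#'   `epsilon_target` (experimental value aimed for, NA for uncorrected
#'   models).
#' @examples
#' solvent_registry()
#' @export
solvent_registry <- function() {
  tibble::tibble(
    name = c("TIP3P", "H2O-DC", "CYH", "CYH-DC"),
    kind = c("aqueous", "aqueous", "nonpolar", "nonpolar"),
    epsilon_model = c(98, 78.4, 1, 2.0),
    epsilon_target = c(NA, 78.4, NA, 2.0)
  )
}

.registry_lookup <- function(name) {
  reg <- solvent_registry()
  row <- reg[reg$name == name, ]
  if (nrow(row) == 0L) {
    .abort(sprintf("Unknown solvent model '%s'; registry knows %s.", name,
                   paste(reg$name, collapse = ", ")), "dielbal_reference_error")
  }
  row
}

#' Check a solvent pair for dielectric balance
#'
#' A (water model, organic model) pair is dielectrically balanced when
#' each model's effective static dielectric constant lies within a
#' fractional tolerance of its experimental target: 78.4 for the
#' aqueous phase and 2.0 for cyclohexane.
#'
#' @param water,organic Solvent model names resolvable in
#'   [solvent_registry()], or one-row data frames in the registry
#'   layout.
#' @param tolerance Fractional tolerance (default 0.1, i.e. 10 %).
#' @return A list: `balanced` (logical) and `report`, a tibble with one
#'   row per solvent giving the effective epsilon, its target and the
#'   fractional deviation.
#' @examples
#' balance_check("H2O-DC", "CYH-DC")$balanced  # TRUE
#' balance_check("TIP3P", "CYH")$balanced      # FALSE
#' @export
balance_check <- function(water, organic, tolerance = 0.1) {
  resolve <- function(x) if (is.character(x)) .registry_lookup(x) else tibble::as_tibble(x)
  targets <- c(aqueous = 78.4, nonpolar = 2.0)
  rows <- dplyr::bind_rows(resolve(water), resolve(organic))
  report <- rows |>
    dplyr::mutate(
      effective_epsilon = .data$epsilon_model,
      target = targets[.data$kind],
      fractional_deviation = abs(.data$effective_epsilon - .data$target) / .data$target,
      within_tolerance = .data$fractional_deviation <= tolerance
    ) |>
    dplyr::select("name", "kind", "effective_epsilon", "target",
                  "fractional_deviation", "within_tolerance")
  list(balanced = all(report$within_tolerance), report = report)
}
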