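# Physical constants, GROMACS-style unit system:
# energies in kJ/mol, lengths in nm, charges in elementary charge (e).

#' Physical constants used throughout dielbal
#'
#' A named list of the constants the package computes with, in the GROMACS
#' unit system (kJ/mol, nm, elementary charge, K):
#'
#' * `R_kJmol`: molar gas constant, 8.31446e-3 kJ/(mol K).
#' * `ln10_literal`: the literal 2.303 denominator constant of the
#'   partition equation as conventionally printed; see [log_partition()]
#'   for the `exact_ln10` switch.
#' * `coulomb_f`: electric conversion factor \eqn{1/(4\pi\epsilon_0)} in
#'   kJ mol^-1 nm e^-2 (138.935458, the GROMACS value).
#' * `eps0`: vacuum permittivity in e^2 mol kJ^-1 nm^-1, i.e.
#'   `1 / (4 * pi * coulomb_f)`.
#' * `debye_per_enm`: Debye per e nm (48.0321), for dipole-unit
#'   presentation.
#'
#' @return A named list of numeric constants.
#' @examples
#' dielbal_constants()$R_kJmol * 298.15 # RT at 298.15 K, ~2.479 kJ/mol
#' @export
dielbal_constants <- function() {
  list(
    R_kJmol = 8.31446e-3,
    ln10_literal = 2.303,
    coulomb_f = 138.935458,
    eps0 = 1 / (4 * pi * 138.935458),
    debye_per_enm = 48.0321
  )
}

.const <- dielbal_constants()
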