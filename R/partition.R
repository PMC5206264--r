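# Water-to-cyclohexane partition: log P = (dG_wat - dG_cyh) / (2.303 R T),
# plus the null baseline and the "say-less" magnitude scaling.

#' log P from a pair of solvation free energies
#'
#' Computes `log P = (dG_wat - dG_cyh) / (2.303 * R * T)` with
#' R = 8.31446e-3 kJ/(mol K). The sign convention is
#' cyclohexane-over-water distribution: favorable hydration (more
#' negative `dG_wat`) gives a negative log P. The denominator uses the
#' conventional literal 2.303; set `exact_ln10 = TRUE` for ln(10)
#' (a 0.02 % difference).
#'
#' @param dG_wat,dG_cyh Air-to-solvent transfer free energies, kJ/mol.
#' @param temperature Absolute temperature in K (default 298.15).
#' @param exact_ln10 Use `log(10)` instead of the literal 2.303.
#' @return Dimensionless log P (vectorised over the inputs).
#' @examples
#' log_partition(-10, -10)                    # 0
#' log_partition(2.303 * 8.31446e-3 * 298.15, 0)  # 1
#' @export
log_partition <- function(dG_wat, dG_cyh, temperature = 298.15,
                          exact_ln10 = FALSE) {
  if (any(temperature <= 0)) {
    .abort("`temperature` must be positive (Kelvin).", "dielbal_value_error")
  }
  denom <- (if (exact_ln10) log(10) else .const$ln10_literal) *
    .const$R_kJmol * temperature
  (dG_wat - dG_cyh) / denom
}

#' Build water-to-cyclohexane transfer records
#'
#' Takes a table of per-solute solvation free energies in the two
#' phases and returns it augmented with the log P estimate of log D and
#' its uncertainty. Leg uncertainties, when supplied, combine in
#' quadrature and convert to log units through the same denominator.
#'
#' @param data Data frame with `solute_id`, `dG_wat`, `dG_cyh` (kJ/mol)
#'   and optionally `unc_wat`, `unc_cyh` (kJ/mol, 1 sigma).
#' @param temperature Kelvin.
#' @param exact_ln10 See [log_partition()].
#' @return Tibble: input columns plus `temperature`, `logP`,
#'   `uncertainty` (log units).
#' @examples
#' transfer_records(data.frame(solute_id = "a", dG_wat = -20, dG_cyh = -10))
#' @export
transfer_records <- function(data, temperature = 298.15, exact_ln10 = FALSE) {
  data <- tibble::as_tibble(data)
  need <- c("solute_id", "dG_wat", "dG_cyh")
  if (!all(need %in% names(data))) {
    .abort(paste("Missing columns:", paste(setdiff(need, names(data)), collapse = ", ")),
           "dielbal_format_error")
  }
  denom <- (if (exact_ln10) log(10) else .const$ln10_literal) *
    .const$R_kJmol * temperature
  unc_wat <- if ("unc_wat" %in% names(data)) data$unc_wat else rep(0, nrow(data))
  unc_cyh <- if ("unc_cyh" %in% names(data)) data$unc_cyh else rep(0, nrow(data))
  dplyr::mutate(
    data,
    temperature = temperature,
    logP = log_partition(.data$dG_wat, .data$dG_cyh, temperature, exact_ln10),
    uncertainty = sqrt(unc_wat^2 + unc_cyh^2) / denom
  )
}

#' Scale solvation free-energy magnitudes ("say less")
#'
#' Multiplies both phases' solvation free energies by `s` and recomputes
#' log P, which therefore scales exactly by `s`. `s = 0.5` is the
#' retrospective 50 % scaling that halves predicted log P magnitudes;
#' `s = 0` collapses every prediction to the null baseline.
#'
#' @param records A transfer-record tibble from [transfer_records()]
#'   (or any frame with `dG_wat`, `dG_cyh`).
#' @param s Scale factor in \[0, 1\].
#' @param temperature,exact_ln10 Passed to [transfer_records()]; the
#'   temperature defaults to the records' own column when present.
#' @return The rescaled transfer-record tibble.
#' @examples
#' r <- transfer_records(data.frame(solute_id = "a", dG_wat = -20, dG_cyh = -10))
#' scale_solvation(r, 0.5)$logP / r$logP # 0.5
#' @export
scale_solvation <- function(records, s, temperature = NULL, exact_ln10 = FALSE) {
  if (s < 0 || s > 1) {
    .abort("`s` must lie in [0, 1].", "dielbal_value_error")
  }
  records <- tibble::as_tibble(records)
  temperature <- temperature %||%
    (if ("temperature" %in% names(records)) records$temperature[1] else 298.15)
  records$dG_wat <- s * records$dG_wat
  records$dG_cyh <- s * records$dG_cyh
  if ("unc_wat" %in% names(records)) records$unc_wat <- s * records$unc_wat
  if ("unc_cyh" %in% names(records)) records$unc_cyh <- s * records$unc_cyh
  transfer_records(records[, setdiff(names(records), c("temperature", "logP", "uncertainty"))],
                   temperature = temperature, exact_ln10 = exact_ln10)
}

#' Null-baseline predictions: log D = 0 for every solute
#'
#' The no-knowledge baseline for a distribution experiment: every solute
#' is assumed to distribute equally between the two phases.
#'
#' @param solute_ids Character vector of solute identifiers.
#' @return Tibble `solute_id`, `predicted` with every prediction 0.
#' @examples
#' null_baseline(c("a", "b", "c"))
#' @export
null_baseline <- function(solute_ids) {
  tibble::tibble(solute_id = as.character(solute_ids), predicted = 0)
}
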