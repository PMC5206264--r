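# TSV interchange formats. All tables are tab-separated with a header
# row; the dipole format carries its box metadata in '#' header lines.

#' Read a per-lambda-window gradient table
#'
#' Long form (`lambda`, `sample`) or summary form
#' (`lambda`, `mean`\[, `stderr`\]) TSV, one file per alchemical leg.
#'
#' @param path TSV file path.
#' @return Tibble in the layout found.
#' @export
read_ti_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#"))
}

#' Read a solvation free-energy table
#'
#' @param path TSV with columns `solute_id`, `dG_wat_kJmol`,
#'   `dG_cyh_kJmol` and optionally `unc_wat_kJmol`, `unc_cyh_kJmol`.
#' @return Tibble renamed to the `transfer_records()` layout
#'   (`solute_id`, `dG_wat`, `dG_cyh`, ...).
#' @export
read_dg_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#"))
  ren <- c(dG_wat = "dG_wat_kJmol", dG_cyh = "dG_cyh_kJmol",
           unc_wat = "unc_wat_kJmol", unc_cyh = "unc_cyh_kJmol")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(d)) names(d)[names(d) == ren[[new]]] <- new
  }
  d
}

#' Read a prediction/experiment table
#'
#' @param path TSV with columns `solute_id`, `predicted`, `experimental`
#'   and optionally `pred_uncertainty`.
#' @return A validated prediction-set tibble.
#' @export
read_predictions_tsv <- function(path) {
  as_prediction_set(utils::read.delim(path, sep = "\t", comment.char = "#"))
}

#' Read a total-dipole time series
#'
#' Expects `#`-prefixed header lines `volume_nm3 <v>` and
#' `temperature_K <T>` followed by a TSV table `frame`, `Mx`, `My`,
#' `Mz` in e nm.
#'
#' @param path TSV file path.
#' @return A `dipole_series`.
#' @export
read_dipoles_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("\\b", key, "\\b"), hdr, value = TRUE)
    if (length(hit) == 0L) {
      .abort(sprintf("Dipole TSV lacks a '# %s <value>' header line.", key),
             "dielbal_format_error")
    }
    as.numeric(sub(paste0(".*", key, "\\s+"), "", hit[1]))
  }
  d <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  dipole_series(d, volume = meta("volume_nm3"), temperature = meta("temperature_K"))
}

#' Write a tibble as TSV
#'
#' @param data Data frame.
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines written
#'   before the table.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(data, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dipole series as TSV
#'
#' @param ds A `dipole_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dipoles_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "dipole_series"))
  d <- tibble::tibble(frame = seq_len(nrow(ds$dipoles)),
                      Mx = ds$dipoles[, "Mx"], My = ds$dipoles[, "My"],
                      Mz = ds$dipoles[, "Mz"])
  write_tsv_table(d, path, header_lines = c(
    sprintf("volume_nm3 %.10g", ds$volume),
    sprintf("temperature_K %.10g", ds$temperature)
  ))
}
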