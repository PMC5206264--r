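# GROMACS .itp subset reader/writer: [atomtypes], [moleculetype], [atoms]
# are parsed; every other section passes through byte-identical.

.abort <- function(msg, class) rlang::abort(msg, class = c(class, "dielbal_error"))

.as_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (is.character(source)) {
    return(unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE))
  }
  .abort("`source` must be a file path, connection, or character vector of lines.",
         "dielbal_value_error")
}

.strip_comment <- function(line) sub(";.*$", "", line)

.section_name <- function(line) {
  m <- regmatches(line, regexec("^\\s*\\[\\s*([A-Za-z0-9_-]+)\\s*\\]\\s*$",
                                .strip_comment(line)))[[1]]
  if (length(m) == 2L) tolower(m[2]) else NA_character_
}

.num_or_abort <- function(tok, what, lineno) {
  x <- suppressWarnings(as.numeric(tok))
  if (is.na(x)) {
    .abort(sprintf("Malformed numeric %s field '%s' on line %d.", what, tok, lineno),
           "dielbal_parse_error")
  }
  x
}

# [atomtypes] lines come in several GROMACS layouts; anchor on the
# single-letter particle-type column, sigma and epsilon follow it.
.parse_atomtypes <- function(lines, linenos) {
  out <- list()
  for (k in seq_along(lines)) {
    body <- trimws(.strip_comment(lines[k]))
    if (!nzchar(body)) next
    toks <- strsplit(body, "\\s+")[[1]]
    ip <- which(toupper(toks) %in% c("A", "S", "V", "D"))
    ip <- ip[ip >= 2 & ip + 2 <= length(toks)]
    if (length(ip) == 0L) {
      .abort(sprintf("Cannot locate particle-type column in [atomtypes] line %d.",
                     linenos[k]), "dielbal_parse_error")
    }
    ip <- ip[length(ip)]
    mass <- if (ip >= 3) suppressWarnings(as.numeric(toks[ip - 2L])) else NA_real_
    out[[toks[1]]] <- list(
      sigma = .num_or_abort(toks[ip + 1L], "sigma", linenos[k]),
      epsilon = .num_or_abort(toks[ip + 2L], "epsilon", linenos[k]),
      mass = mass
    )
  }
  out
}

#' Read a GROMACS-dialect molecule topology
#'
#' Parses the `[atoms]` section (and, when present, `[moleculetype]` and
#' `[atomtypes]`) of a GROMACS `.itp`/`.top` file into a
#' `molecule_topology` object. Every section the package does not model --
#' bonds, angles, dihedrals, pairs, exclusions -- is kept verbatim and
#' written back byte-identically, so the only fields the dielectric
#' modulation can touch are per-atom charges and Lennard-Jones sigma.
#'
#' Per-atom sigma/epsilon are resolved from the `[atomtypes]` section of
#' the same stream, or from a second stream passed as `atomtypes` (GAFF
#' topologies commonly keep atom types in a separate file).
#'
#' @param source File path, connection, or character vector of lines.
#' @param atomtypes Optional second source containing an `[atomtypes]`
#'   section used to resolve sigma/epsilon (same accepted forms).
#' @return A `molecule_topology`: a list with `name`, an `atoms` tibble
#'   (`index`, `type_name`, `resnr`, `residue`, `atom_name`, `cgnr`,
#'   `charge` in e, `sigma` in nm, `epsilon` in kJ/mol, `mass` in amu),
#'   `passthrough_blocks` (verbatim text of unmodelled sections), and a
#'   `provenance` character vector.
#' @seealso [write_topology()], [net_charge()], [apply_gdb()]
#' @examples
#' top <- gen_topology(4, net_charge = 0, seed = 1)
#' f <- tempfile(fileext = ".itp")
#' write_topology(top, f)
#' read_topology(f)
#' @export
read_topology <- function(source, atomtypes = NULL) {
  lines <- .as_lines(source)
  n <- length(lines)
  sec <- character(n)
  cur <- ""
  for (i in seq_len(n)) {
    s <- .section_name(lines[i])
    if (!is.na(s)) cur <- s
    sec[i] <- cur
  }

  if (!any(sec == "atoms")) {
    .abort("No [atoms] section found in topology source.", "dielbal_format_error")
  }

  types <- list()
  if (any(sec == "atomtypes")) {
    idx <- which(sec == "atomtypes" & is.na(vapply(lines, .section_name, "")))
    types <- .parse_atomtypes(lines[idx], idx)
  }
  if (!is.null(atomtypes)) {
    at_lines <- .as_lines(atomtypes)
    at_sec <- .section_name(at_lines)
    body <- which(is.na(vapply(at_lines, .section_name, "")))
    types <- utils::modifyList(types, .parse_atomtypes(at_lines[body], body))
  }

  name <- "MOL"
  mt_idx <- which(sec == "moleculetype" & is.na(vapply(lines, .section_name, "")))
  for (i in mt_idx) {
    body <- trimws(.strip_comment(lines[i]))
    if (nzchar(body)) {
      name <- strsplit(body, "\\s+")[[1]][1]
      break
    }
  }

  atom_idx <- which(sec == "atoms" & is.na(vapply(lines, .section_name, "")))
  recs <- list()
  for (i in atom_idx) {
    body <- trimws(.strip_comment(lines[i]))
    if (!nzchar(body)) next
    toks <- strsplit(body, "\\s+")[[1]]
    if (length(toks) < 7L) {
      .abort(sprintf("Expected at least 7 fields in [atoms] line %d, got %d.",
                     i, length(toks)), "dielbal_parse_error")
    }
    tname <- toks[2]
    tt <- types[[tname]]
    if (is.null(tt)) {
      .abort(sprintf("Atom type '%s' (line %d) not resolvable from any [atomtypes] section.",
                     tname, i), "dielbal_reference_error")
    }
    mass <- if (length(toks) >= 8L) .num_or_abort(toks[8], "mass", i) else tt$mass
    if (is.na(mass)) {
      .abort(sprintf("No mass for atom on line %d (neither [atoms] nor [atomtypes] give one).",
                     i), "dielbal_parse_error")
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      index = as.integer(.num_or_abort(toks[1], "index", i)),
      type_name = tname,
      resnr = as.integer(.num_or_abort(toks[3], "residue number", i)),
      residue = toks[4],
      atom_name = toks[5],
      cgnr = as.integer(.num_or_abort(toks[6], "charge group", i)),
      charge = .num_or_abort(toks[7], "charge", i),
      sigma = tt$sigma,
      epsilon = tt$epsilon,
      mass = mass
    )
  }
  atoms <- dplyr::bind_rows(recs)
  if (nrow(atoms) == 0L) {
    .abort("The [atoms] section contains no atom lines.", "dielbal_format_error")
  }
  if (anyDuplicated(atoms$index)) {
    .abort("Duplicate atom indices in [atoms] section.", "dielbal_format_error")
  }

  handled <- c("atoms", "atomtypes", "moleculetype")
  prov <- grep("^; dielbal:", lines, value = TRUE)
  keep <- (sec != "" & !(sec %in% handled)) |
    (sec == "" & nzchar(trimws(lines)) & !grepl("^; dielbal:", lines))
  passthrough <- character(0)
  if (any(keep)) {
    blocks <- split(lines[keep], cumsum(!is.na(vapply(lines[keep], .section_name, ""))))
    passthrough <- vapply(blocks, paste, "", collapse = "\n")
    names(passthrough) <- vapply(blocks, function(b) .section_name(b[1]) %||% "preamble", "")
  }

  new_molecule_topology(name, atoms, passthrough,
                        provenance = sub("^; dielbal: ", "", prov))
}

#' Construct a molecule_topology from parts
#'
#' @param name Molecule name for `[moleculetype]`.
#' @param atoms Data frame with at least `index`, `type_name`, `residue`,
#'   `atom_name`, `charge`, `sigma`, `epsilon`, `mass`. `resnr`/`cgnr`
#'   default to 1 and the atom index.
#' @param passthrough_blocks Named character vector of verbatim section
#'   text preserved on write.
#' @param provenance Character vector of provenance notes.
#' @return A validated `molecule_topology` object.
#' @export
new_molecule_topology <- function(name, atoms, passthrough_blocks = character(0),
                                  provenance = character(0)) {
  atoms <- tibble::as_tibble(atoms)
  if (!"resnr" %in% names(atoms)) atoms$resnr <- 1L
  if (!"cgnr" %in% names(atoms)) atoms$cgnr <- as.integer(atoms$index)
  ord <- c("index", "type_name", "resnr", "residue", "atom_name", "cgnr",
           "charge", "sigma", "epsilon", "mass")
  extra <- setdiff(names(atoms), ord)
  atoms <- atoms[, c(ord, extra)]
  top <- structure(
    list(name = as.character(name), atoms = atoms,
         passthrough_blocks = passthrough_blocks,
         provenance = as.character(provenance)),
    class = "molecule_topology"
  )
  validate_topology(top)
  top
}

#' Validate a molecule_topology's invariants
#'
#' Checks the structural invariants: unique 1-based atom indices,
#' non-negative sigma and epsilon, positive mass, and that the stored
#' atoms table is non-empty.
#'
#' @param top A `molecule_topology`.
#' @return `top`, invisibly; aborts on violation.
#' @export
validate_topology <- function(top) {
  stopifnot(inherits(top, "molecule_topology"))
  a <- top$atoms
  if (nrow(a) == 0L) .abort("Topology has no atoms.", "dielbal_format_error")
  if (anyDuplicated(a$index)) .abort("Atom indices are not unique.", "dielbal_format_error")
  if (any(a$sigma < 0)) .abort("Negative Lennard-Jones sigma.", "dielbal_value_error")
  if (any(a$epsilon < 0)) .abort("Negative Lennard-Jones epsilon.", "dielbal_value_error")
  if (any(a$mass <= 0)) .abort("Non-positive atomic mass.", "dielbal_value_error")
  invisible(top)
}

#' Net charge of a molecule topology
#'
#' @param top A `molecule_topology`.
#' @return The exact sum of atomic partial charges, in elementary charge.
#' @examples
#' net_charge(gen_topology(6, net_charge = -1, seed = 2))
#' @export
net_charge <- function(top) {
  stopifnot(inherits(top, "molecule_topology"))
  sum(top$atoms$charge)
}

# Per-atom sigma inflation can split one atom type into several (sigma,
# epsilon) pairs; derived type names keep the output a legal .itp.
.atomtype_table <- function(atoms) {
  key <- paste(atoms$type_name, signif(atoms$sigma, 10), signif(atoms$epsilon, 10))
  uk <- !duplicated(key)
  tab <- atoms[uk, c("type_name", "sigma", "epsilon", "mass")]
  tab$key <- key[uk]
  dup <- tab$type_name %in% tab$type_name[duplicated(tab$type_name)]
  tab$out_name <- tab$type_name
  for (tn in unique(tab$type_name[dup])) {
    sel <- which(tab$type_name == tn)
    tab$out_name[sel] <- paste0(tn, "_m", seq_along(sel))
  }
  list(table = tab, atom_out = tab$out_name[match(key, tab$key)])
}

#' Write a molecule topology as a GROMACS-dialect .itp file
#'
#' Emits `[atomtypes]`, `[moleculetype]` and `[atoms]` sections followed
#' by all passthrough blocks byte-identically. Charges are written with 6
#' decimal places and sigma/epsilon with 7 significant figures, so a
#' write/read round trip reproduces the numeric fields to well under
#' 1e-6. Provenance notes (e.g. the charge scale factor of an applied
#' modulation) are written as `; dielbal:` comment lines.
#'
#' If a modulation has given atoms of one atom type distinct sigma
#' values, derived type names (`_m1`, `_m2`, ...) are emitted so the file
#' stays legal.
#'
#' @param top A `molecule_topology`.
#' @param sink File path or connection.
#' @return The path or connection, invisibly.
#' @seealso [read_topology()]
#' @export
write_topology <- function(top, sink) {
  validate_topology(top)
  a <- top$atoms
  tt <- .atomtype_table(a)
  out <- character(0)
  if (length(top$provenance)) {
    out <- c(out, paste0("; dielbal: ", top$provenance))
  }
  out <- c(out, "[ atomtypes ]",
           "; name    mass    charge  ptype   sigma(nm)   epsilon(kJ/mol)")
  out <- c(out, sprintf("%-8s %10.4f %8.4f  A  %12.7g %12.7g",
                        tt$table$out_name, tt$table$mass, 0, tt$table$sigma,
                        tt$table$epsilon))
  out <- c(out, "", "[ moleculetype ]", "; name  nrexcl", sprintf("%s   3", top$name),
           "", "[ atoms ]",
           ";  nr  type  resnr residue atom cgnr    charge      mass")
  out <- c(out, sprintf("%5d %-8s %4d %-6s %-6s %4d %12.6f %12.6f",
                        a$index, tt$atom_out, a$resnr, a$residue, a$atom_name,
                        a$cgnr, a$charge, a$mass))
  for (blk in top$passthrough_blocks) out <- c(out, "", blk)
  if (inherits(sink, "connection")) {
    writeLines(out, sink)
  } else {
    writeLines(out, con = sink)
  }
  invisible(sink)
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("<molecule_topology> %s: %d atoms, net charge %+.4f e\n",
              x$name, nrow(x$atoms), net_charge(x)))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  print(x$atoms, n = 5)
  invisible(x)
}

#' Tidy a molecule topology into its atoms table
#'
#' @param x A `molecule_topology`.
#' @param ... Unused.
#' @return The atoms tibble, one row per atom.
#' @method tidy molecule_topology
#' @export
tidy.molecule_topology <- function(x, ...) x$atoms
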