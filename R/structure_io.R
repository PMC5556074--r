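# Structure input: PDB parsing (via bio3d) restricted to protein atoms,
# and assembly of a validated two-partner complex.

#' Parse a PDB structure to protein atoms
#'
#' Reads PDB-format text (or a file) and returns only atoms belonging to
#' the 20 standard amino acids. Waters, ligands and nucleic acids are
#' dropped; common modified residues (e.g. MSE) are mapped to their
#' parent standard residue; other non-standard residues are dropped with
#' a warning. For alternate locations the highest-occupancy copy of each
#' atom is kept (ties: first encountered). Hydrogens, if present, are
#' kept: contact counts at 2.5 Angstrom are hydrogen-sensitive, so
#' structures with and without protons give different counts there.
#'
#' @param pdb PDB-format text as a single string or character vector of
#'   lines, or a path to a PDB file.
#' @return A data.frame of atoms with columns `name`, `element`, `x`,
#'   `y`, `z`, `chain_id`, `res_seq`, `i_code`, `res_name`, `alt_loc`,
#'   `occupancy`.
#' @export
parse_structure <- function(pdb) {
  lines <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }

  rec <- grepl("^(ATOM  |HETATM)", lines)
  # Validate coordinate fields (columns 31-54) before handing to the parser
  # so a malformed line is reported by number.
  for (i in which(rec)) {
    coords <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      hs_error("hs_parse_error",
               sprintf("malformed coordinate fields on line %d: %s",
                       i, trimws(lines[i])),
               line = i)
    }
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb_obj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) hs_error("hs_parse_error",
                                 paste("PDB parse failed:", conditionMessage(e))))
  at <- pdb_obj$atom

  # Map modified residues onto their parent, then keep standard ones only.
  mapped <- at$resid %in% names(NONSTANDARD_MAP)
  at$resid[mapped] <- NONSTANDARD_MAP[at$resid[mapped]]
  nonstd <- !(at$resid %in% AA3)
  dropped <- setdiff(unique(at$resid[nonstd & at$type == "ATOM"]), c("HOH", "DOD"))
  if (length(dropped) > 0) {
    hs_warn("hs_nonstandard_dropped",
            paste("dropped non-standard residues:", paste(dropped, collapse = ", ")))
  }
  at <- at[!nonstd, , drop = FALSE]
  if (nrow(at) == 0) {
    hs_error("hs_parse_error", "no protein atoms found in input")
  }

  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # Alternate locations: keep highest occupancy per atom site, first on ties.
  site <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(site, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(site[ord]), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert), , drop = FALSE]

  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  # Fall back to the leading letter of the atom name (PDB convention).
  element[missing_el] <- substring(gsub("[^A-Za-z].*", "", at$elety[missing_el]), 1, 1)

  data.frame(
    name = at$elety, element = element,
    x = at$x, y = at$y, z = at$z,
    chain_id = at$chain, res_seq = at$resno, i_code = at$insert,
    res_name = at$resid, alt_loc = at$alt, occupancy = at$o,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write atoms back to PDB text
#'
#' Inverse of [parse_structure()] for round-trip checks and fixture
#' generation: emits standard fixed-column ATOM records.
#'
#' @param atoms Atom data.frame as returned by [parse_structure()].
#' @return Character vector of PDB lines (including END).
#' @export
write_structure <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, atoms$alt_loc, atoms$res_name,
    atoms$chain_id, atoms$res_seq, atoms$i_code,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element)
  c(lines, "END")
}

#' Assemble a two-partner complex
#'
#' Partitions parsed atoms into two disjoint chain groups. The order of
#' the two groups is arbitrary: every downstream feature is symmetric
#' under exchanging them. Chains named in neither group are dropped with
#' a warning.
#'
#' @param atoms Atom data.frame from [parse_structure()].
#' @param group_a,group_b Character vectors of chain identifiers.
#' @param source_id Free-text structure identifier carried into reports.
#' @return A `complex_structure` object: list with `atoms`, `group_a`,
#'   `group_b`, `source_id`.
#' @export
build_complex <- function(atoms, group_a, group_b, source_id = "complex") {
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  if (length(group_a) == 0 || length(group_b) == 0) {
    hs_error("hs_validation_error", "both chain groups must be non-empty")
  }
  overlap <- intersect(group_a, group_b)
  if (length(overlap) > 0) {
    hs_error("hs_validation_error",
             paste("chain groups overlap:", paste(overlap, collapse = ", ")))
  }
  present <- unique(atoms$chain_id)
  absent <- setdiff(c(group_a, group_b), present)
  if (length(absent) > 0) {
    hs_error("hs_validation_error",
             paste("chain id(s) absent from structure:", paste(absent, collapse = ", ")))
  }
  unused <- setdiff(present, c(group_a, group_b))
  if (length(unused) > 0) {
    hs_warn("hs_chains_dropped",
            paste("chains in neither group dropped:", paste(unused, collapse = ", ")))
    atoms <- atoms[atoms$chain_id %in% c(group_a, group_b), , drop = FALSE]
  }
  for (g in list(group_a, group_b)) {
    if (nrow(atoms[atoms$chain_id %in% g, , drop = FALSE]) == 0) {
      hs_error("hs_validation_error", "a chain group contains no residues")
    }
  }
  structure(list(atoms = atoms, group_a = group_a, group_b = group_b,
                 source_id = source_id),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure '%s': %d atoms, group A = {%s}, group B = {%s}>\n",
              x$source_id, nrow(x$atoms),
              paste(x$group_a, collapse = ","), paste(x$group_b, collapse = ",")))
  invisible(x)
}

# Residue identity key: author numbering preserved end-to-end.
res_key <- function(chain, resno, icode = "") {
  paste(chain, resno, icode, sep = ":")
}

atom_res_keys <- function(atoms) {
  res_key(atoms$chain_id, atoms$res_seq, atoms$i_code)
}

# Atoms belonging to one chain group.
group_atoms <- function(cx, group = c("a", "b")) {
  ids <- if (match.arg(group) == "a") cx$group_a else cx$group_b
  cx$atoms[cx$atoms$chain_id %in% ids, , drop = FALSE]
}

# One row per residue: key, chain, resno, icode, res_name, group.
residue_table <- function(cx) {
  keys <- atom_res_keys(cx$atoms)
  first <- !duplicated(keys)
  data.frame(
    key = keys[first],
    chain = cx$atoms$chain_id[first],
    resno = cx$atoms$res_seq[first],
    icode = cx$atoms$i_code[first],
    resname = cx$atoms$res_name[first],
    group = ifelse(cx$atoms$chain_id[first] %in% cx$group_a, "A", "B"),
    stringsAsFactors = FALSE
  )
}
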