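# Structure-based residue features: interface detection by SASA burial,
# the 12 SASA-derived features, intermolecular contact counts and
# hydrophobic contacts, and the complex-level interface composition.

#' Interfacial residues of a complex
#'
#' A residue is interfacial when it loses solvent accessible surface
#' area upon complexation: monomer SASA minus complex SASA > `tol`.
#' The definition is symmetric in the two chain groups.
#'
#' @param cx A `complex_structure`.
#' @param profile Optional precomputed [sasa_profile()] (recomputed when
#'   `NULL`).
#' @param tol Burial tolerance, Angstrom^2.
#' @param ... Passed to [sasa_profile()].
#' @return Character vector of residue keys (`chain:resno:icode`).
#' @export
interface_residues <- function(cx, profile = NULL, tol = 1e-6, ...) {
  if (is.null(profile)) profile <- sasa_profile(cx, ...)
  keys <- profile$key[(profile$mon - profile$comp) > tol]
  if (length(keys) == 0) {
    hs_error("hs_no_interface",
             "no interface: no residue buried upon complexation")
  }
  keys
}

#' Twelve SASA features for one residue
#'
#' Absolute, relative and ratio SASA descriptors for a residue, from the
#' bound/unbound SASA profile:
#' complex SASA, monomer SASA, delta SASA (each also normalized by the
#' residue type's theoretical maximum SASA), side-chain complex/monomer/
#' delta SASA, fraction buried (delta/monomer, 0 when the monomer value
#' is 0), and the residue's complex and monomer SASA relative to the
#' mean over residues of the same type in the same state.
#'
#' @param key Residue key.
#' @param profile [sasa_profile()] output.
#' @param restype_reference Max-SASA table (named by three-letter code).
#' @return Named numeric vector of length 12.
#' @export
sasa_feature_vector <- function(key, profile,
                                restype_reference = max_sasa_reference()) {
  i <- match(key, profile$key)
  if (is.na(i)) hs_error("hs_validation_error", paste("residue not in profile:", key))
  rn <- profile$resname[i]
  mx <- unname(restype_reference[rn])
  if (is.na(mx)) {
    hs_error("hs_validation_error", paste("unknown residue type:", rn))
  }
  comp <- profile$comp[i]; mon <- profile$mon[i]
  dsasa <- mon - comp
  same <- profile$resname == rn
  mean_comp <- mean(profile$comp[same])
  mean_mon <- mean(profile$mon[same])
  c(sasa_comp = comp,
    sasa_mon = mon,
    sasa_delta = dsasa,
    rel_comp = comp / mx,
    rel_mon = mon / mx,
    rel_delta = dsasa / mx,
    sc_comp = profile$comp_sc[i],
    sc_mon = profile$mon_sc[i],
    sc_delta = profile$mon_sc[i] - profile$comp_sc[i],
    frac_buried = if (mon > 0) dsasa / mon else 0,
    ratio_comp_type = if (mean_comp > 0) comp / mean_comp else 0,
    ratio_mon_type = if (mean_mon > 0) mon / mean_mon else 0)
}

# Squared distances between two atom coordinate matrices.
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Intermolecular atomic contacts per residue
#'
#' For every residue, the number of atom pairs (one atom in the residue,
#' one in the opposite chain group) within `cutoff` Angstrom.
#'
#' @param cx A `complex_structure`.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Named integer vector over all residue keys of the complex.
#' @export
contact_counts <- function(cx, cutoff) {
  if (cutoff <= 0) hs_error("hs_validation_error", "cutoff must be positive")
  at_a <- group_atoms(cx, "a")
  at_b <- group_atoms(cx, "b")
  d2 <- cross_dist2(as.matrix(at_a[, c("x", "y", "z")]),
                    as.matrix(at_b[, c("x", "y", "z")]))
  hit <- d2 <= cutoff^2 + 1e-12
  keys_a <- atom_res_keys(at_a)
  keys_b <- atom_res_keys(at_b)
  res <- residue_table(cx)
  counts <- setNames(integer(nrow(res)), res$key)
  ca <- tapply(rowSums(hit), keys_a, sum)
  cb <- tapply(colSums(hit), keys_b, sum)
  counts[names(ca)] <- as.integer(ca)
  counts[names(cb)] <- as.integer(cb)
  counts
}

#' Intermolecular hydrophobic contacts per residue
#'
#' Counts carbon-carbon intermolecular atom pairs within `cutoff`
#' (default 4.5 Angstrom) where both atoms belong to residues of the
#' apolar set (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO).
#'
#' @param cx A `complex_structure`.
#' @param cutoff Distance cutoff, Angstrom.
#' @param hydrophobic_set Three-letter codes treated as apolar.
#' @return Named integer vector over all residue keys of the complex.
#' @export
hydrophobic_contacts <- function(cx, cutoff = 4.5,
                                 hydrophobic_set = HYDROPHOBIC_SET) {
  pick <- function(at) at[at$res_name %in% hydrophobic_set &
                            at$element == "C", , drop = FALSE]
  at_a <- pick(group_atoms(cx, "a"))
  at_b <- pick(group_atoms(cx, "b"))
  res <- residue_table(cx)
  counts <- setNames(integer(nrow(res)), res$key)
  if (nrow(at_a) > 0 && nrow(at_b) > 0) {
    d2 <- cross_dist2(as.matrix(at_a[, c("x", "y", "z")]),
                      as.matrix(at_b[, c("x", "y", "z")]))
    hit <- d2 <= cutoff^2 + 1e-12
    ca <- tapply(rowSums(hit), atom_res_keys(at_a), sum)
    cb <- tapply(colSums(hit), atom_res_keys(at_b), sum)
    counts[names(ca)] <- as.integer(ca)
    counts[names(cb)] <- as.integer(cb)
  }
  counts
}

#' Interface amino-acid composition
#'
#' Counts interfacial residues of the whole complex by amino-acid type.
#' This is a protein-level feature: the same 20-vector is attached to
#' every residue observation of the complex.
#'
#' @param cx A `complex_structure`.
#' @param interface Optional precomputed interface residue keys.
#' @param ... Passed to [interface_residues()].
#' @return Named integer vector of length 20 (three-letter codes); sums
#'   to the number of interfacial residues.
#' @export
interface_composition <- function(cx, interface = NULL, ...) {
  if (is.null(interface)) interface <- interface_residues(cx, ...)
  res <- residue_table(cx)
  rn <- res$resname[match(interface, res$key)]
  counts <- setNames(integer(length(AA3)), AA3)
  tab <- table(rn)
  counts[names(tab)] <- as.integer(tab)
  counts
}
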