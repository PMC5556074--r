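# Shrake-Rupley solvent accessible surface area.
#
# Each atom is inflated by the probe radius and sampled with a fixed,
# deterministic quasi-uniform point set (golden-section spiral); a sample
# point is accessible when it lies outside every neighbouring inflated
# sphere. Per-atom SASA = inflated-sphere area x accessible fraction.

# Deterministic quasi-uniform points on the unit sphere.
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-atom SASA for a coordinate matrix and radii vector.
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  r_inf <- radii + probe
  out <- numeric(n)
  # Neighbour search via cell-free cutoff: the largest possible contact
  # distance between inflated spheres.
  max_reach <- 2 * max(r_inf)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_inf[i] + r_inf)^2 & d2 > 1e-12)
    p <- pts * r_inf[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r_inf[j]^2
    }
    out[i] <- 4 * pi * r_inf[i]^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue solvent accessible surface area
#'
#' Computes Shrake-Rupley SASA (probe 1.4 Angstrom by default) for a set
#' of atoms and aggregates it per residue, both in total and for the
#' side chain (all atoms except backbone N, CA, C, O/OXT and backbone
#' hydrogens).
#'
#' @param atoms Atom data.frame from [parse_structure()].
#' @param probe Probe radius, Angstrom.
#' @param n_points Number of quadrature points per atom sphere.
#' @param radii Named van der Waals radius table by element, Angstrom.
#' @return A data.frame with one row per residue: `key`, `resname`,
#'   `total` and `side_chain` SASA in Angstrom^2.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960,
                         radii = vdw_radii()) {
  if (nrow(atoms) == 0) hs_error("hs_validation_error", "no atoms")
  r <- radii[atoms$element]
  r[is.na(r)] <- radii[["C"]]
  per_atom <- shrake_rupley(as.matrix(atoms[, c("x", "y", "z")]), r,
                            probe = probe, n_points = n_points)
  keys <- atom_res_keys(atoms)
  side <- !(atoms$name %in% BACKBONE_ATOMS)
  total <- tapply(per_atom, keys, sum)
  sc <- tapply(per_atom * side, keys, sum)
  first <- !duplicated(keys)
  ord <- keys[first]
  data.frame(
    key = ord,
    resname = atoms$res_name[first],
    total = as.numeric(total[ord]),
    side_chain = as.numeric(sc[ord]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Complex and monomer SASA profile
#'
#' Runs the SASA computation once on the whole complex and once on each
#' isolated chain group, giving per-residue SASA in the bound and
#' unbound states. Burial on binding is `monomer - complex >= 0` (up to
#' quadrature noise).
#'
#' @param cx A `complex_structure`.
#' @inheritParams compute_sasa
#' @return A data.frame with one row per residue: `key`, `resname`,
#'   `group`, `comp`, `mon`, `comp_sc`, `mon_sc` (Angstrom^2).
#' @export
sasa_profile <- function(cx, probe = 1.4, n_points = 960, radii = vdw_radii()) {
  comp <- compute_sasa(cx$atoms, probe, n_points, radii)
  mon_a <- compute_sasa(group_atoms(cx, "a"), probe, n_points, radii)
  mon_b <- compute_sasa(group_atoms(cx, "b"), probe, n_points, radii)
  mon <- rbind(mon_a, mon_b)
  m <- match(comp$key, mon$key)
  res <- residue_table(cx)
  data.frame(
    key = comp$key,
    resname = comp$resname,
    group = res$group[match(comp$key, res$key)],
    comp = comp$total,
    mon = mon$total[m],
    comp_sc = comp$side_chain,
    mon_sc = mon$side_chain[m],
    stringsAsFactors = FALSE
  )
}
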