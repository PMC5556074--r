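# Synthetic data generators. These define the test-bench conditions for
# the whole pipeline: a geometric two-chain complex with a controllable
# contact patch, labelled feature tables with the dataset's class
# imbalance (~24% HS), and a full-size synthetic stand-in for the
# labelled training table (534 observations from 53 complexes, 127 HS /
# 407 NS, 881 feature columns).

#' Generate a synthetic two-chain complex
#'
#' Builds two extended poly-residue chains (5 atoms per residue: N, CA,
#' C, O, CB; no CB for GLY) running along x. Chain B lies parallel to
#' chain A at height `separation` (CA-plane to CA-plane, Angstrom), with
#' CB side chains of the two chains pointing at each other, and is
#' shifted along x so that exactly `patch_size` residue pairs overlap.
#' Residues outside the overlap drift apart in x, so the contact patch
#' is controllable. The generator records, from its own coordinates and
#' by direct pair enumeration, which residues have intermolecular atoms
#' within 4.0 Angstrom (the oracle for interface and contact tests).
#'
#' @param n_res Residues per chain (scalar or length 2).
#' @param separation CA-plane separation, Angstrom (5.5 puts facing CB
#'   atoms ~3.5 Angstrom apart; 30 gives no interface).
#' @param patch_size Number of aligned residue pairs (default: full
#'   overlap of the shorter chain).
#' @param sequence Three-letter residue codes, recycled along each
#'   chain (default poly-ALA).
#' @param chain_ids Two chain identifiers.
#' @param jitter Uniform coordinate noise amplitude, Angstrom.
#' @param seed Integer seed.
#' @return List: `pdb` (PDB text lines), `patch_a`, `patch_b` (aligned
#'   residue keys), `contact_residues` (keys with any intermolecular
#'   atom pair <= 4 Angstrom), `n_atoms`.
#' @export
make_synthetic_complex <- function(n_res = 12, separation = 5.5,
                                   patch_size = NULL, sequence = "ALA",
                                   chain_ids = c("A", "B"), jitter = 0.05,
                                   seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_res <- rep_len(n_res, 2)
  if (is.null(patch_size)) patch_size <- min(n_res)
  patch_size <- min(patch_size, min(n_res))

  build_chain <- function(n, chain, z0, cb_dir, x0) {
    seqs <- rep_len(sequence, n)
    rows <- list()
    for (i in seq_len(n)) {
      ca <- c(x0 + 3.8 * (i - 1), 0, z0)
      atoms <- rbind(
        N = ca + c(-1.20, 0.80, 0),
        CA = ca,
        C = ca + c(1.20, 0.80, 0),
        O = ca + c(1.20, 2.00, 0),
        CB = ca + c(0, 0, cb_dir * 1.0))
      el <- c("N", "C", "C", "O", "C")
      keep <- if (seqs[i] == "GLY") 1:4 else 1:5
      rows[[i]] <- data.frame(
        name = rownames(atoms)[keep], element = el[keep],
        x = atoms[keep, 1], y = atoms[keep, 2], z = atoms[keep, 3],
        chain_id = chain, res_seq = i, i_code = "", res_name = seqs[i],
        alt_loc = "", occupancy = 1, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  # Chain B overlaps the last patch_size residues of chain A.
  x_off <- 3.8 * (n_res[1] - patch_size)
  at_a <- build_chain(n_res[1], chain_ids[1], 0, +1, 0)
  at_b <- build_chain(n_res[2], chain_ids[2], separation, -1, x_off)
  atoms <- rbind(at_a, at_b)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    matrix(stats::runif(3 * nrow(atoms), -jitter, jitter), ncol = 3)
  rownames(atoms) <- NULL

  # Oracle by direct pair enumeration over the generator's coordinates.
  a_idx <- atoms$chain_id == chain_ids[1]
  xa <- as.matrix(atoms[a_idx, c("x", "y", "z")])
  xb <- as.matrix(atoms[!a_idx, c("x", "y", "z")])
  contact <- character(0)
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) <= 4.0) {
        contact <- union(contact, c(atom_res_keys(atoms[a_idx, ])[i],
                                    atom_res_keys(atoms[!a_idx, ])[j]))
      }
    }
  }

  list(
    pdb = write_structure(atoms),
    atoms = atoms,
    patch_a = res_key(chain_ids[1], seq(n_res[1] - patch_size + 1, n_res[1])),
    patch_b = res_key(chain_ids[2], seq_len(patch_size)),
    contact_residues = contact,
    n_atoms = nrow(atoms)
  )
}

#' Generate a labelled synthetic feature table
#'
#' Draws HS/NS labels with the dataset's class imbalance and Gaussian
#' features; the first `n_informative` features get a mean shift of
#' `effect_size` for HS observations (effect size 0 makes any model's
#' expected AUROC 0.5). A ddG column consistent with the labels (HS >=
#' 2 kcal/mol) and complex/chain/residue identity columns are included,
#' so the table exercises the same loading and labelling paths as real
#' data.
#'
#' @param n_obs Number of observations.
#' @param hs_fraction Expected fraction of HS labels (binomial draw).
#' @param n_features Total feature columns.
#' @param n_informative Number of class-shifted features.
#' @param effect_size Class mean shift of informative features, in SD
#'   units.
#' @param n_complexes Number of distinct complex identifiers.
#' @param seed Integer seed.
#' @return Feature table with identity columns, `ddg`, `class` and
#'   features `f001`...; attribute `informative` names the shifted
#'   columns.
#' @export
make_synthetic_table <- function(n_obs = 534, hs_fraction = 0.24,
                                 n_features = 60, n_informative = 10,
                                 effect_size = 1.0, n_complexes = 53,
                                 seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  is_hs <- stats::rbinom(n_obs, 1, hs_fraction)
  if (all(is_hs == 0)) is_hs[1] <- 1
  if (all(is_hs == 1)) is_hs[1] <- 0
  x <- matrix(stats::rnorm(n_obs * n_features), n_obs, n_features)
  n_informative <- min(n_informative, n_features)
  if (n_informative > 0) {
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
      effect_size * is_hs
  }
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  ddg <- ifelse(is_hs == 1, 2 + stats::rexp(n_obs, 1),
                stats::runif(n_obs, -1, 1.99))
  tab <- cbind(
    data.frame(
      complex = sprintf("CPX%02d", sample.int(n_complexes, n_obs, replace = TRUE)),
      chain = "A", resno = seq_len(n_obs), icode = "",
      resname = sample(AA3, n_obs, replace = TRUE),
      ddg = ddg, class = ifelse(is_hs == 1, "HS", "NS"),
      stringsAsFactors = FALSE),
    as.data.frame(x))
  attr(tab, "informative") <- colnames(x)[seq_len(n_informative)]
  tab
}

#' Synthetic stand-in for the labelled training dataset
#'
#' A synthetic table with the exact published composition of the
#' training data: 534 observations from 53 complexes, exactly 127
#' hot-spots (ddG >= 2 kcal/mol) and 407 null-spots, and 881 feature
#' columns. The feature values are synthetic draws (`n_informative`
#' class-shifted Gaussians among noise); only the bookkeeping
#' composition matches the real dataset, not its measured values.
#'
#' @param seed Integer seed.
#' @param n_informative Number of informative feature columns.
#' @param effect_size Class mean shift of informative features.
#' @param path Optional CSV output path.
#' @return The feature table (invisibly also written to `path` if
#'   given).
#' @export
make_synthetic_dataset1 <- function(seed = 1, n_informative = 40,
                                    effect_size = 1.2, path = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 534; n_hs <- 127; n_cpx <- 53; n_feat <- 881
  is_hs <- integer(n)
  is_hs[sample.int(n, n_hs)] <- 1
  cpx <- sprintf("CPX%02d", rep_len(seq_len(n_cpx), n))
  x <- matrix(stats::rnorm(n * n_feat), n, n_feat)
  x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
    effect_size * is_hs
  colnames(x) <- sprintf("f%04d", seq_len(n_feat))
  ddg <- ifelse(is_hs == 1, 2 + stats::rexp(n, 1), stats::runif(n, -1, 1.99))
  tab <- cbind(
    data.frame(complex = cpx, chain = "A", resno = seq_len(n), icode = "",
               resname = sample(AA3, n, replace = TRUE), ddg = ddg,
               stringsAsFactors = FALSE),
    as.data.frame(x))
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(tab)
}
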