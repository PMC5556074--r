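# Feature assembly: one row per interfacial residue, combining the
# structural module (SASA, contacts, interface composition) with the
# sequence module (AAC/PAAC/APAAC/scale covariances per chain group,
# PSSM per residue position).

#' Extract the full feature table of a complex
#'
#' Computes every enabled feature for every interfacial residue of the
#' complex. Residue-level features are the 12 SASA descriptors, the
#' contact counts at the two cutoffs, the hydrophobic contact count and
#' (when profiles are given) the 40 PSSM features at the residue's own
#' position. Protein-level features (interface composition for the
#' complex; AAC, PAAC, amphiphilic PAAC and scale covariances for the
#' residue's chain group) are attached identically to every residue
#' observation they describe. All features are symmetric under swapping
#' the two chain groups.
#'
#' @param cx A `complex_structure`.
#' @param paac_lambda,paac_w Pseudo-AAC order and weight; every chain
#'   group sequence must be longer than `paac_lambda`.
#' @param scales,scales_lag Scale matrix and maximum lag for
#'   [scales_descriptor()].
#' @param pssm Optional named list of `pssm_profile` objects, one per
#'   chain id. When `NULL` or missing for a chain, the 40 PSSM features
#'   are imputed as 0 and the `pssm_imputed` column flags the rows.
#' @param n_points SASA quadrature points.
#' @param probe SASA probe radius, Angstrom.
#' @return A data.frame: identity columns (`complex`, `chain`, `resno`,
#'   `icode`, `resname`) followed by numeric feature columns.
#' @export
extract_features <- function(cx, paac_lambda = 30, paac_w = 0.05,
                             scales = blosum_scales(), scales_lag = 7,
                             pssm = NULL, n_points = 960, probe = 1.4) {
  profile <- sasa_profile(cx, probe = probe, n_points = n_points)
  iface <- interface_residues(cx, profile = profile)
  res <- residue_table(cx)
  res <- res[match(iface, res$key), , drop = FALSE]

  c25 <- contact_counts(cx, 2.5)
  c40 <- contact_counts(cx, 4.0)
  hyd <- hydrophobic_contacts(cx)
  comp20 <- interface_composition(cx, interface = iface)

  # Per chain-group sequences: chains concatenated in author order.
  seqs <- chain_sequences(cx)
  group_of_chain <- ifelse(names(seqs) %in% cx$group_a, "A", "B")
  group_seq <- vapply(c(A = "A", B = "B"), function(g) {
    paste(seqs[group_of_chain == g], collapse = "")
  }, character(1))

  seq_feats <- lapply(group_seq, function(s) {
    c(setNames(aac(s), paste0("aac_", AA1)),
      setNames(paac(s, paac_lambda, paac_w),
               paste0("paac_", c(AA1, paste0("lam", seq_len(paac_lambda))))),
      setNames(apaac(s, paac_lambda, paac_w),
               paste0("apaac_", c(AA1, paste0("tau", seq_len(2 * paac_lambda))))),
      setNames(scales_descriptor(s, scales, scales_lag),
               paste0("blosum_", names(scales_descriptor(s, scales, scales_lag)))))
  })

  # Residue position within its own chain, for PSSM lookup.
  all_res <- residue_table(cx)
  pos_in_chain <- stats::ave(seq_len(nrow(all_res)), all_res$chain,
                             FUN = seq_along)
  names(pos_in_chain) <- all_res$key

  rows <- lapply(seq_len(nrow(res)), function(i) {
    k <- res$key[i]
    sv <- sasa_feature_vector(k, profile)
    contact <- c(n_contacts_2p5 = unname(c25[k]),
                 n_contacts_4p0 = unname(c40[k]),
                 n_hydrophobic = unname(hyd[k]))
    pr <- pssm[[res$chain[i]]]
    if (is.null(pr)) {
      pv <- setNames(numeric(40), c(paste0("pssm_", AA1), paste0("wop_", AA1)))
      imputed <- 1
    } else {
      pv <- pssm_features(pr, pos_in_chain[[k]])
      imputed <- 0
    }
    c(sv, contact, setNames(comp20, paste0("ifc_", AA3)),
      seq_feats[[res$group[i]]], pv, pssm_imputed = imputed)
  })
  feats <- do.call(rbind, rows)
  cbind(
    data.frame(complex = cx$source_id, chain = res$chain, resno = res$resno,
               icode = res$icode, resname = res$resname,
               stringsAsFactors = FALSE),
    as.data.frame(feats)
  )
}
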