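# Sequence-based descriptors: amino-acid composition, Chou's pseudo
# amino-acid composition (plain and amphiphilic), substitution-matrix
# scale auto/cross-covariances, and PSSM profile features.

check_sequence <- function(seq) {
  letters1 <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(letters1 %in% AA1))
  if (length(bad) > 0) {
    hs_error("hs_validation_error",
             sprintf("invalid amino-acid letter '%s' at position %d",
                     letters1[bad[1]], bad[1]))
  }
  letters1
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 amino-acid types in a sequence.
#'
#' @param seq One-letter amino-acid sequence (single string).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aac <- function(seq) {
  letters1 <- check_sequence(seq)
  if (length(letters1) == 0) hs_error("hs_validation_error", "empty sequence")
  counts <- setNames(numeric(20), AA1)
  tab <- table(letters1)
  counts[names(tab)] <- as.numeric(tab)
  counts / length(letters1)
}

# Standardize a property scale over the 20 amino acids with the
# population (n-denominator) standard deviation, per Chou's convention.
standardize_scale <- function(p) {
  p <- p[AA1]
  (p - mean(p)) / sqrt(mean((p - mean(p))^2))
}

#' Pseudo amino-acid composition (Chou's PAAC)
#'
#' The 20 composition terms plus `lambda` sequence-order correlation
#' factors computed from standardized hydrophobicity, hydrophilicity and
#' side-chain-mass scales. The correlation factor at rank j averages the
#' mean squared property difference between residues j positions apart.
#' All 20 + lambda entries are normalized to sum to 1.
#'
#' @param seq One-letter amino-acid sequence.
#' @param lambda Maximum sequence-order rank (`length(seq) > lambda`).
#' @param w Weight of the sequence-order terms.
#' @return Named numeric vector of length `20 + lambda`.
#' @export
paac <- function(seq, lambda = 30, w = 0.05) {
  letters1 <- check_sequence(seq)
  n <- length(letters1)
  if (n <= lambda) {
    hs_error("hs_validation_error",
             sprintf("sequence length %d too short for lambda %d", n, lambda))
  }
  if (w <= 0) hs_error("hs_validation_error", "w must be positive")
  scales <- rbind(standardize_scale(PAAC_HYDROPHOBICITY),
                  standardize_scale(PAAC_HYDROPHILICITY),
                  standardize_scale(PAAC_SIDECHAIN_MASS))
  props <- scales[, letters1, drop = FALSE]
  theta <- vapply(seq_len(lambda), function(j) {
    d <- props[, (1 + j):n, drop = FALSE] - props[, 1:(n - j), drop = FALSE]
    mean(colMeans(d^2))
  }, numeric(1))
  f <- aac(seq)
  denom <- sum(f) + w * sum(theta)
  out <- c(f, w * theta) / denom
  names(out) <- c(AA1, paste0("lambda", seq_len(lambda)))
  out
}

#' Amphiphilic pseudo amino-acid composition
#'
#' As [paac()] but with separate hydrophobicity and hydrophilicity
#' correlation channels: for each rank j the mean product of
#' standardized hydrophobicity values j apart (tau_{2j-1}) and of
#' hydrophilicity values (tau_{2j}), giving `2 * lambda` sequence-order
#' terms.
#'
#' @inheritParams paac
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
apaac <- function(seq, lambda = 30, w = 0.05) {
  letters1 <- check_sequence(seq)
  n <- length(letters1)
  if (n <= lambda) {
    hs_error("hs_validation_error",
             sprintf("sequence length %d too short for lambda %d", n, lambda))
  }
  if (w <= 0) hs_error("hs_validation_error", "w must be positive")
  h1 <- standardize_scale(PAAC_HYDROPHOBICITY)[letters1]
  h2 <- standardize_scale(PAAC_HYDROPHILICITY)[letters1]
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    tau[2 * j - 1] <- mean(h1[1:(n - j)] * h1[(1 + j):n])
    tau[2 * j] <- mean(h2[1:(n - j)] * h2[(1 + j):n])
  }
  f <- aac(seq)
  denom <- sum(f) + w * sum(tau)
  out <- c(f, w * tau) / denom
  names(out) <- c(AA1, paste0("tau", seq_len(2 * lambda)))
  out
}

#' Default substitution-matrix scales
#'
#' Top principal components of the BLOSUM62 substitution matrix over the
#' 20 standard amino acids: each residue type is described by its scores
#' on the first `k` components. Signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param k Number of components.
#' @return 20 x k numeric matrix, rows named by one-letter code.
#' @export
blosum_scales <- function(k = 5) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b <- env$BLOSUM62[AA1, AA1]
  pc <- stats::prcomp(b, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(sc))) {
    if (sc[which.max(abs(sc[, j])), j] < 0) sc[, j] <- -sc[, j]
  }
  rownames(sc) <- AA1
  colnames(sc) <- paste0("pc", seq_len(k))
  sc
}

#' Scale auto/cross-covariance descriptor
#'
#' Projects each residue of the sequence onto `k` per-residue property
#' scales, centers each projected component over the sequence, and
#' returns all auto- and cross-covariances up to `lag`:
#' C_ab(l) = mean_i z_i[a] * z_{i+l}[b]. Output length is `k^2 * lag`.
#' Alternative scale matrices (fingerprinting, proteochemometric) plug
#' in through `scales` with the same contract.
#'
#' @param seq One-letter amino-acid sequence.
#' @param scales 20 x k matrix of per-residue-type scales (rows named by
#'   one-letter code); default BLOSUM62 principal components.
#' @param lag Maximum lag (`lag < length(seq)`).
#' @return Named numeric vector of length `k^2 * lag`.
#' @export
scales_descriptor <- function(seq, scales = blosum_scales(), lag = 7) {
  letters1 <- check_sequence(seq)
  n <- length(letters1)
  if (lag >= n) {
    hs_error("hs_validation_error",
             sprintf("lag %d must be smaller than sequence length %d", lag, n))
  }
  z <- scales[letters1, , drop = FALSE]
  z <- sweep(z, 2, colMeans(z), "-")
  k <- ncol(z)
  out <- numeric(k * k * lag)
  nm <- character(k * k * lag)
  idx <- 1
  for (l in seq_len(lag)) {
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        out[idx] <- mean(z[1:(n - l), a] * z[(1 + l):n, b])
        nm[idx] <- sprintf("%s_%s_lag%d", colnames(scales)[a], colnames(scales)[b], l)
        idx <- idx + 1
      }
    }
  }
  setNames(out, nm)
}

#' Read an ASCII PSSM profile
#'
#' Parses the standard ASCII output of a profile search (one row per
#' sequence position: 20 log-odds scores then 20 weighted observed
#' percentages).
#'
#' @param path Path to the ASCII profile file.
#' @param n_homologs Number of homologous sequences behind the profile,
#'   if known (the file format does not carry it).
#' @return A `pssm_profile` object: list with `sequence` (one-letter
#'   vector), `scores` and `percentages` (n x 20 matrices), `n_homologs`.
#' @export
read_pssm <- function(path, n_homologs = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*\\d+\\s+[A-Z]\\s", lines, value = TRUE)
  if (length(rows) == 0) hs_error("hs_parse_error", "no profile rows found")
  parts <- strsplit(trimws(rows), "\\s+")
  ok <- vapply(parts, function(p) length(p) >= 42, logical(1))
  parts <- parts[ok]
  seq1 <- vapply(parts, `[[`, character(1), 2)
  num <- t(vapply(parts, function(p) as.numeric(p[3:42]), numeric(40)))
  new_pssm_profile(num[, 1:20, drop = FALSE], num[, 21:40, drop = FALSE],
                   seq1, n_homologs)
}

#' Construct a PSSM profile object
#'
#' @param scores n x 20 log-odds matrix.
#' @param percentages n x 20 weighted observed percentage matrix.
#' @param sequence One-letter residue vector of length n.
#' @param n_homologs Homolog count behind the profile.
#' @return A `pssm_profile` object.
#' @export
new_pssm_profile <- function(scores, percentages, sequence,
                             n_homologs = NA_integer_) {
  stopifnot(ncol(scores) == 20, ncol(percentages) == 20,
            nrow(scores) == nrow(percentages),
            nrow(scores) == length(sequence))
  colnames(scores) <- paste0("pssm_", AA1)
  colnames(percentages) <- paste0("wop_", AA1)
  structure(list(scores = scores, percentages = percentages,
                 sequence = sequence, n_homologs = n_homologs),
            class = "pssm_profile")
}

#' Forty PSSM features at one position
#'
#' The 20 log-odds scores plus the 20 weighted observed percentages at a
#' residue's own sequence position. Profiles built from too few homologs
#' are rejected, mirroring the behaviour of profile-based servers.
#'
#' @param profile A `pssm_profile`.
#' @param position 1-based sequence position.
#' @param min_homologs Minimum homolog count accepted (ignored when the
#'   profile's count is unknown).
#' @return Named numeric vector of length 40.
#' @export
pssm_features <- function(profile, position, min_homologs = 10) {
  if (!is.na(profile$n_homologs) && profile$n_homologs < min_homologs) {
    hs_error("hs_insufficient_homologs",
             sprintf("profile built from %d homologs (< %d required)",
                     profile$n_homologs, min_homologs))
  }
  if (position < 1 || position > nrow(profile$scores)) {
    hs_error("hs_validation_error",
             sprintf("position %d outside profile of length %d",
                     position, nrow(profile$scores)))
  }
  c(profile$scores[position, ], profile$percentages[position, ])
}

#' Chain-group sequences of a complex
#'
#' One-letter sequence per chain, in author residue-number order.
#'
#' @param cx A `complex_structure`.
#' @return Named character vector (one sequence per chain id).
#' @export
chain_sequences <- function(cx) {
  res <- residue_table(cx)
  one <- standard_amino_acids()[res$resname]
  vapply(split(one, res$chain)[unique(res$chain)], paste, character(1),
         collapse = "")
}
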