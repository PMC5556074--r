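# Independent oracles used across the suite. Each one is a deliberately
# naive second implementation (brute-force loops, literal formula
# transcriptions) kept separate from the package code paths it checks.

# All-pairs intermolecular contact count per residue, by direct loops.
oracle_contact_counts <- function(atoms, group_a, cutoff) {
  in_a <- atoms$chain_id %in% group_a
  keys <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, sep = ":")
  counts <- setNames(integer(length(unique(keys))), unique(keys))
  ia <- which(in_a); ib <- which(!in_a)
  for (i in ia) for (j in ib) {
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    if (d <= cutoff) {
      counts[keys[i]] <- counts[keys[i]] + 1L
      counts[keys[j]] <- counts[keys[j]] + 1L
    }
  }
  counts
}

# Literal transcription of Chou's pseudo amino-acid composition.
oracle_paac <- function(seq, lambda, w) {
  aa <- sort(c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y"))
  std <- function(p) { p <- p[aa]; (p - mean(p)) / sqrt(sum((p - mean(p))^2) / 20) }
  h1 <- std(hotspotr:::PAAC_HYDROPHOBICITY)
  h2 <- std(hotspotr:::PAAC_HYDROPHILICITY)
  h3 <- std(hotspotr:::PAAC_SIDECHAIN_MASS)
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(n - j)) {
      acc <- acc + ((h1[s[i]] - h1[s[i + j]])^2 + (h2[s[i]] - h2[s[i + j]])^2 +
                      (h3[s[i]] - h3[s[i + j]])^2) / 3
    }
    theta[j] <- acc / (n - j)
  }
  f <- sapply(aa, function(a) sum(s == a) / n)
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

# Literal transcription of the amphiphilic pseudo amino-acid composition.
oracle_apaac <- function(seq, lambda, w) {
  aa <- sort(c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y"))
  std <- function(p) { p <- p[aa]; (p - mean(p)) / sqrt(sum((p - mean(p))^2) / 20) }
  h1 <- std(hotspotr:::PAAC_HYDROPHOBICITY)
  h2 <- std(hotspotr:::PAAC_HYDROPHILICITY)
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    tau[2 * j - 1] <- sum(h1[s[1:(n - j)]] * h1[s[(1 + j):n]]) / (n - j)
    tau[2 * j] <- sum(h2[s[1:(n - j)]] * h2[s[(1 + j):n]]) / (n - j)
  }
  f <- sapply(aa, function(a) sum(s == a) / n)
  unname(c(f, w * tau) / (sum(f) + w * sum(tau)))
}

# Independent arithmetic transcription of the confusion-count metrics.
oracle_metrics <- function(tp, tn, fp, fn) {
  c(Accuracy = (tp + tn) / (tp + fp + fn + tn),
    TPR = tp / (tp + fn),
    TNR = tn / (fp + tn),
    PPV = tp / (tp + fp),
    NPV = tn / (tn + fn),
    FDR = fp / (fp + tp),
    FNR = fn / (tp + fn),
    F1 = 2 * tp / (2 * tp + fp + fn),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# AUROC by exhaustive pair counting over HS x NS pairs.
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth == "HS"]; neg <- scores[truth == "NS"]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# A tiny hand-built PDB: helper to write raw records.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = " ", element = substr(name, 1, 1),
                     record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resname, chain, resno,
          x, y, z, occ, 0, element)
}

# Minimal 5-atom residue at an offset.
residue_lines <- function(serial0, resname, chain, resno, ox, oy = 0, oz = 0) {
  c(pdb_line(serial0, "N", resname, chain, resno, ox - 1.2, oy + 0.8, oz),
    pdb_line(serial0 + 1, "CA", resname, chain, resno, ox, oy, oz),
    pdb_line(serial0 + 2, "C", resname, chain, resno, ox + 1.2, oy + 0.8, oz),
    pdb_line(serial0 + 3, "O", resname, chain, resno, ox + 1.2, oy + 2.0, oz),
    pdb_line(serial0 + 4, "CB", resname, chain, resno, ox, oy - 1.0, oz + 1.0,
             element = "C"))
}
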