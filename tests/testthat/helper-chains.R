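# build toy chain records and PDB files in code

# straight-ish resolved trace so superpositions are well-posed
toy_chain <- function(id, aa, resolved = rep(TRUE, length(aa)), seed = 1) {
  n <- length(aa)
  xyz <- flexkit::make_hinge_conformer(max(2, ceiling(n / 2)), 0)$xyz[seq_len(n), ]
  xyz[!resolved, ] <- NA_real_
  flexkit::chain_record(id, aa, xyz)
}

random_aa <- function(n, seed) {
  set.seed(seed)
  sample(c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE)
}

# minimal hand-written PDB text with SEQRES and CA atoms
write_mini_pdb <- function(path, chains) {
  # chains: named list chain_id -> list(seqres = 3-letter vec, ca = data.frame(resno, resid, x, y, z))
  lines <- character(0)
  for (ch in names(chains)) {
    sr <- chains[[ch]]$seqres
    if (!is.null(sr)) {
      idx <- split(seq_along(sr), ceiling(seq_along(sr) / 13))
      for (k in seq_along(idx))
        lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", k, ch, length(sr),
                                  paste(sr[idx[[k]]], collapse = " ")))
    }
  }
  serial <- 0
  for (ch in names(chains)) {
    ca <- chains[[ch]]$ca
    for (r in seq_len(nrow(ca))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, ca$resid[r], ch, ca$resno[r], ca$x[r], ca$y[r], ca$z[r]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}

helix_ca <- function(resno, resid = rep("ALA", length(resno))) {
  k <- seq_along(resno) - 1
  data.frame(resno = resno, resid = resid,
             x = 2.3 * cos(k * 100 * pi / 180),
             y = 2.3 * sin(k * 100 * pi / 180),
             z = 1.42 * k)
}
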