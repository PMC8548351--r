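# Text fixtures built in code at test time.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fixture_fasta <- function() {
  write_lines_tmp(c(">a first protein", "ACD", ">b", "AC", "DEF"), ".fasta")
}

fixture_afa <- function() {
  write_lines_tmp(c(">q", "ACDEF", ">r1", "AC-EF", ">r2", "GCDEF"), ".afa")
}

fixture_a3m <- function() {
  # query ACD; second row has a lowercase insertion
  write_lines_tmp(c(">q", "ACD", ">r1", "AcCD", ">r2", "A-D"), ".a3m")
}

# 5-residue ASCII PSSM in the PSI-BLAST layout (20 score columns then
# 20 weighted-percentage columns truncated to two to keep rows short)
fixture_pssm <- function() {
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(c("A", "R", "N", "D", "C", "Q", "E", "G",
                                  "H", "I", "L", "K", "M", "F", "P", "S",
                                  "T", "W", "Y", "V"), collapse = "   ")))
  scores <- rbind(
    c(5, -2, -1, -2, -1, -1, -1, 0, -2, -2, -2, -1, -1, -3, -1, 1, 0, -3, -2, -1),
    c(-1, -4, -2, -4, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1),
    c(-2, -2, 1, 6, -4, 0, 2, -1, -1, -3, -4, -1, -3, -4, -1, 0, -1, -5, -3, -4),
    c(-1, 0, 0, 2, -4, 2, 5, -2, 0, -4, -3, 1, -2, -3, -1, 0, -1, -3, -2, -3),
    c(-3, -3, -3, -4, -2, -4, -3, -4, -1, 0, 0, -4, 0, 7, -4, -3, -2, 1, 3, -1))
  aa <- c("A", "C", "D", "E", "F")
  rows <- vapply(1:5, function(i) {
    paste0(sprintf("%5d %s ", i, aa[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = " "),
           "   0   0")
  }, character(1))
  list(path = write_lines_tmp(c(header, rows, ""), ".pssm"), scores = scores,
       residues = paste(aa, collapse = ""))
}

# Minimal hand-written PDB: 3 ALA residues with full N/CA/C, the CA of
# residue 2 present in two altlocs (A occ 0.6, B occ 0.4).
fixture_pdb <- function() {
  atom <- function(serial, name, alt, resno, x, y, z, occ) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), alt, "ALA", "A", resno, " ",
            x, y, z, occ, 0.0, substr(name, 1, 1))
  }
  ch <- esiden::build_backbone(c(0, -60, -120), c(-45, 130, 0))
  lines <- character(0)
  serial <- 0
  for (r in 1:3) {
    for (nm in c("N", "CA", "C")) {
      xyz <- ch$coords[[r]][nm, ]
      serial <- serial + 1
      if (r == 2 && nm == "CA") {
        lines <- c(lines,
                   atom(serial, nm, "A", r, xyz[1], xyz[2], xyz[3], 0.6),
                   atom(serial + 100, nm, "B", r, xyz[1] + 5, xyz[2], xyz[3], 0.4))
      } else {
        lines <- c(lines, atom(serial, nm, " ", r, xyz[1], xyz[2], xyz[3], 1.0))
      }
    }
  }
  list(path = write_lines_tmp(c(lines, "END"), ".pdb"), chain = ch)
}

# tiny two-class toy dataset for fast network tests
tiny_dataset <- function(n = 4, L = 12, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- matrix(stats::rnorm(L * 232, sd = 0.3), L, 232)
    phi <- ifelse(x[, 1] > 0, -60, -120) + stats::rnorm(L, sd = 3)
    psi <- ifelse(x[, 1] > 0, -45, 130) + stats::rnorm(L, sd = 3)
    ts <- new_torsion_series(phi, psi)
    enc <- encode_targets(ts)
    list(x = x, y = enc$targets, mask = enc$mask)
  })
}

tiny_config <- function(seed = 1, dropout = 0) {
  model_config(input_width = 232, lstm1_hidden = 8, bilstm_hidden = 8,
               bilstm2_hidden = 8, fc1_units = 16, fc1_dropout = dropout,
               seed = seed)
}
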