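# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they cross-check.

# binary KL divergence evaluated term by term, scalar loop
oracle_relative_entropy <- function(freqs, background) {
  L <- nrow(freqs)
  out <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    for (a in seq_len(20)) {
      f <- freqs[i, a]; p <- background[a]
      t1 <- if (f > 0) f * log(f / p) else 0
      t2 <- if (f < 1) (1 - f) * log((1 - f) / (1 - p)) else 0
      out[i, a] <- t1 + t2
    }
  }
  out
}

# softmax computed with explicit exp/sum loop (no max-shift trick)
oracle_softmax <- function(h) {
  out <- matrix(0, nrow(h), ncol(h))
  for (i in seq_len(nrow(h))) {
    e <- exp(h[i, ])
    out[i, ] <- e / sum(e)
  }
  out
}

# plane-normal arccos dihedral with separately computed sign
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ca <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) ang <- -ang
  ang
}

# Eq.-style wrap-aware MAE as an explicit double loop over chains/residues
oracle_mae <- function(pred_list, ref_list, angle = c("phi", "psi")) {
  angle <- match.arg(angle)
  mask_col <- paste0(angle, "_mask")
  total <- 0; count <- 0
  for (i in seq_along(pred_list)) {
    p <- pred_list[[i]]; e <- ref_list[[i]]
    for (j in seq_len(nrow(p))) {
      if (p[[mask_col]][j] && e[[mask_col]][j]) {
        d <- abs(p[[angle]][j] - e[[angle]][j])
        total <- total + min(d, 360 - d)
        count <- count + 1
      }
    }
  }
  total / count
}

# shorter-arc difference used to compare two angles near the +-180 seam
angdiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# analytic parameter count for the network topology
oracle_param_count <- function(cfg) {
  lstm <- function(I, H) 4 * H * (I + H + 1)
  I <- cfg$input_width
  lstm(I, cfg$lstm1_hidden) +
    2 * lstm(I, cfg$bilstm_hidden) +
    2 * lstm(cfg$lstm1_hidden + 2 * cfg$bilstm_hidden, cfg$bilstm2_hidden) +
    (2 * cfg$bilstm2_hidden * cfg$fc1_units + cfg$fc1_units) +
    (cfg$fc1_units * 4 + 4)
}
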