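# Synthetic fixtures: conservation-controlled alignments, ideal-geometry
# backbones built from prescribed torsions, and an end-to-end toy dataset
# whose angles carry a sequence signal the network can learn.

# Ideal backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

SS_CLASSES <- list(
  H = list(phi = -63, psi = -42,
           alphabet = c("A", "E", "L", "M", "Q", "K", "R")),
  E = list(phi = -120, psi = 130,
           alphabet = c("V", "I", "F", "Y", "W", "T", "C")),
  C = list(phi = -75, psi = 150,
           alphabet = c("G", "N", "P", "S", "D"))
)

#' Specification of the synthetic study conditions
#'
#' Defines what the generator emulates: a set of protein chains with
#' segmental secondary structure whose residue composition differs by
#' class (so sequence predicts local conformation), alignments with
#' controllable per-column conservation, and wrapped-normal angle noise.
#'
#' @param n_chains Number of chains.
#' @param length_range Two integers, inclusive chain-length range.
#' @param msa_depth Rows sampled per alignment (query excluded).
#' @param conservation Per-column probability mass concentrated on the
#'   query residue (scalar, recycled over columns).
#' @param gap_rate Per-cell gap probability in sampled rows.
#' @param angle_noise_sd Wrapped-normal noise sd, degrees.
#' @param seed Integer seed; every derived quantity is reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chains = 50L, length_range = c(30L, 60L),
                           msa_depth = 30L, conservation = 0.85,
                           gap_rate = 0.05, angle_noise_sd = 8,
                           seed = 1L) {
  stopifnot(n_chains >= 1, length_range[1] >= 5,
            length_range[2] >= length_range[1],
            conservation >= 0, conservation <= 1,
            angle_noise_sd >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 length_range = as.integer(length_range),
                 msa_depth = as.integer(msa_depth),
                 conservation = conservation,
                 gap_rate = gap_rate,
                 angle_noise_sd = angle_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample one integer uniformly from [a, b] (safe when a == b)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(lo:hi, 1)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

# secondary-structure segments and matching sequence/angles for one chain
sample_chain_plan <- function(L, noise_sd) {
  ss <- character(0)
  while (length(ss) < L) {
    cl <- sample(names(SS_CLASSES), 1, prob = c(0.4, 0.3, 0.3))
    ss <- c(ss, rep(cl, sample_range(4L, 12L)))
  }
  ss <- ss[seq_len(L)]
  aa <- vapply(ss, function(cl) sample(SS_CLASSES[[cl]]$alphabet, 1),
               character(1), USE.NAMES = FALSE)
  phi <- wrap_angle(vapply(ss, function(cl) SS_CLASSES[[cl]]$phi, numeric(1)) +
                      stats::rnorm(L, sd = noise_sd))
  psi <- wrap_angle(vapply(ss, function(cl) SS_CLASSES[[cl]]$psi, numeric(1)) +
                      stats::rnorm(L, sd = noise_sd))
  list(ss = ss, aa = aa, phi = phi, psi = psi)
}

#' Generate a synthetic alignment with controlled conservation
#'
#' Samples a query from the background distribution (or uses `query`),
#' then, per column, draws a column distribution from a Dirichlet whose
#' concentration mixes the query residue (weight `conservation`) with the
#' background, and samples `msa_depth` rows i.i.d. from it, adding gaps
#' at `gap_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @param query Optional `esiden_sequence` to use as the query.
#' @param conservation Optional per-column conservation vector overriding
#'   the spec's scalar.
#' @return An `aligned_msa` with `msa_depth + 1` rows.
#' @export
make_synthetic_msa <- function(spec, query = NULL, conservation = NULL) {
  with_seed(spec$seed, generate_msa(spec, query, conservation))
}

# unseeded worker so callers composing a larger seeded pipeline can reuse it
generate_msa <- function(spec, query = NULL, conservation = NULL) {
  bg <- aa_background()
  if (is.null(query)) {
    L <- sample_range(spec$length_range[1], spec$length_range[2])
    query <- new_sequence("synthetic_query",
                          paste(sample(AA_ALPHABET, L, replace = TRUE,
                                       prob = bg), collapse = ""))
  }
  qchars <- seq_chars(query)
  L <- length(qchars)
  cons <- conservation %||% rep(spec$conservation, L)
  cons <- rep_len(cons, L)
  rows <- matrix("-", spec$msa_depth, L)
  kappa <- 20
  for (j in seq_len(L)) {
    onehot <- as.numeric(AA_ALPHABET == qchars[[j]])
    if (!any(onehot == 1)) onehot <- bg  # 'X' column: background only
    alpha <- kappa * (cons[[j]] * onehot + (1 - cons[[j]]) * bg) + 1e-3
    p <- rdirichlet1(alpha)
    rows[, j] <- sample(AA_ALPHABET, spec$msa_depth, replace = TRUE, prob = p)
    gaps <- stats::runif(spec$msa_depth) < spec$gap_rate
    rows[gaps, j] <- "-"
  }
  all_rows <- c(query$residues, apply(rows, 1, paste, collapse = ""))
  new_aligned_msa(all_rows,
                  ids = c(query$id, sprintf("synth%03d", seq_len(spec$msa_depth))))
}

# NeRF atom placement: position d with |cd| = bond, angle(b,c,d) = theta,
# dihedral(a,b,c,d) = chi (degrees).
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a backbone from prescribed torsions
#'
#' Constructs N/CA/C coordinates with ideal bond lengths and angles and a
#' planar trans peptide (omega = 180 degrees), so that extracting
#' torsions from the result reproduces the prescribed (phi, psi) to
#' within numerical precision. `phi[1]` and `psi[L]` are ignored
#' (undefined at the termini).
#'
#' @param phi,psi Prescribed angles in degrees, equal length L >= 2.
#' @param aa Optional residue letters (default poly-alanine).
#' @param chain_id Chain identifier.
#' @return A `backbone_chain`.
#' @export
build_backbone <- function(phi, psi, aa = NULL, chain_id = "A") {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  if (is.null(aa)) aa <- rep("A", L)
  coords <- vector("list", L)
  atom_mat <- function() matrix(NA_real_, 3, 3,
                                dimnames = list(c("N", "CA", "C"),
                                                c("x", "y", "z")))
  m <- atom_mat()
  m["N", ] <- c(0, 0, 0)
  m["CA", ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  m["C", ] <- m["CA", ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  coords[[1]] <- m
  for (i in seq_len(L - 1L)) {
    prev <- coords[[i]]
    n_next <- place_atom(prev["N", ], prev["CA", ], prev["C", ],
                         BOND_C_N, ANGLE_CA_C_N, psi[[i]])
    ca_next <- place_atom(prev["CA", ], prev["C", ], n_next,
                          BOND_N_CA, ANGLE_C_N_CA, 180)
    c_next <- place_atom(prev["C", ], n_next, ca_next,
                         BOND_CA_C, ANGLE_N_CA_C, phi[[i + 1L]])
    m <- atom_mat()
    m["N", ] <- n_next; m["CA", ] <- ca_next; m["C", ] <- c_next
    coords[[i + 1L]] <- m
  }
  new_backbone_chain(chain_id = chain_id, aa = aa, coords = coords,
                     complete = rep(TRUE, L))
}

#' Generate a synthetic backbone with segmental secondary structure
#'
#' Samples helix/strand/coil segments, draws (phi, psi) from the class
#' means with wrapped-normal noise, and builds ideal-geometry coordinates
#' from them.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `chain` (`backbone_chain`), `torsions` (the
#'   prescribed `torsion_series`) and `ss` (per-residue Q3 labels).
#' @export
make_synthetic_backbone <- function(spec) {
  with_seed(spec$seed, {
    L <- sample_range(spec$length_range[1], spec$length_range[2])
    plan <- sample_chain_plan(L, spec$angle_noise_sd)
    chain <- build_backbone(plan$phi, plan$psi, aa = plan$aa)
    list(chain = chain,
         torsions = new_torsion_series(plan$phi, plan$psi, aa = plan$aa),
         ss = plan$ss)
  })
}

# synthetic PSI-BLAST-like log-odds from smoothed column frequencies
synthetic_pssm <- function(profile) {
  f <- profile$freqs
  p <- profile$background
  depth <- pmax(profile$effective_depth, 1)
  fs <- (f * depth + 1) / (depth + 20)
  round(2 * log2(sweep(fs, 2, p, "/")))
}

#' Generate the end-to-end toy dataset
#'
#' The full pipeline on synthetic inputs: chains with class-structured
#' sequences and angles, alignments at the spec's conservation,
#' evolutionary features (RE, DC, PSSP), synthetic PSSMs, a basin
#' potential built from the chains' own backbones and reduced with PCA,
#' assembly into scaled L x 232 matrices, and sin/cos targets with
#' terminal masks.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `examples` (list of `list(x, y, mask)` ready for
#'   [train_model()]), `torsions`, `ss`, `sequences`, `scaler`,
#'   `potential`, `reduced`.
#' @export
make_toy_dataset <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_chains
    plans <- vector("list", n)
    for (i in seq_len(n)) {
      L <- sample_range(spec$length_range[1], spec$length_range[2])
      plans[[i]] <- sample_chain_plan(L, spec$angle_noise_sd)
    }
    chains <- lapply(plans, function(p) build_backbone(p$phi, p$psi, aa = p$aa))
    torsions <- lapply(plans, function(p)
      new_torsion_series(p$phi, p$psi, aa = p$aa))
    records <- collect_torsion_records(chains, torsions)
    potential <- build_basin_potential(records)
    reduced <- reduce_basins(potential, method = "pca", seed = spec$seed)

    raw <- vector("list", n)
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      seq <- new_sequence(sprintf("chain%03d", i),
                          paste(plans[[i]]$aa, collapse = ""))
      seqs[[i]] <- seq
      msa <- generate_msa(spec, query = seq)
      profile <- column_frequencies(msa, pseudocount = 1)
      re <- relative_entropy(profile)
      dc <- degree_of_conservation(re)
      pssp <- pssp_from_fields(fit_site_fields(profile))
      pssm <- synthetic_pssm(profile)
      rbp <- rbp_features(seq, reduced)
      raw[[i]] <- assemble_features(seq, pssm, re, dc, pssp, rbp)
    }
    scaler <- fit_scaler(lapply(raw, unclass))
    examples <- vector("list", n)
    for (i in seq_len(n)) {
      x <- apply_scaler(scaler, unclass(raw[[i]]))
      enc <- encode_targets(torsions[[i]])
      examples[[i]] <- list(x = x, y = enc$targets, mask = enc$mask)
    }
    list(examples = examples, torsions = torsions,
         ss = lapply(plans, function(p) p$ss), sequences = seqs,
         scaler = scaler, potential = potential, reduced = reduced)
  })
}
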