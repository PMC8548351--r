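# Classic per-residue features and assembly of all blocks into the
# L x 232 network input, with [-1, 1] min-max channel scaling.

FEATURE_BLOCKS <- c(AA = 20L, PP = 7L, PSSM = 20L, RE = 20L, DC = 1L,
                    PSSP = 20L, RBP = 144L)

block_slices <- function() {
  ends <- cumsum(FEATURE_BLOCKS)
  starts <- ends - FEATURE_BLOCKS + 1L
  stats::setNames(Map(function(s, e) s:e, starts, ends), names(FEATURE_BLOCKS))
}

#' One-hot amino-acid encoding
#'
#' Columns follow the canonical alphabetical one-letter order; `'X'` rows
#' are all zeros.
#'
#' @param seq An `esiden_sequence`.
#' @return An L x 20 numeric matrix.
#' @export
aa_onehot <- function(seq) {
  chars <- seq_chars(seq)
  m <- matrix(0, length(chars), 20L, dimnames = list(NULL, AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Physicochemical feature block
#'
#' Per-residue lookup of the packaged seven-descriptor table
#' ([aa_physchem_table()]); `'X'` rows take the per-property mean over the
#' 20 amino acids.
#'
#' @param seq An `esiden_sequence`.
#' @return An L x 7 numeric matrix.
#' @export
physchem_features <- function(seq) {
  tab <- aa_physchem_table()
  chars <- seq_chars(seq)
  idx <- match(chars, rownames(tab))
  m <- matrix(rep(colMeans(tab), each = length(chars)), length(chars), 7L)
  ok <- !is.na(idx)
  m[ok, ] <- tab[idx[ok], ]
  colnames(m) <- colnames(tab)
  m
}

#' Fit a per-channel min-max scaler
#'
#' Learns per-channel (min, max) bounds on stacked training blocks for the
#' affine map onto `[-1, 1]`. Channels listed in `identity_blocks` (already
#' in range by construction, e.g. one-hot) and constant channels (with a
#' warning) are flagged identity and passed through unchanged.
#'
#' @param x A numeric matrix of stacked rows (sum of chain lengths x 232),
#'   or a list of per-chain matrices that are row-bound.
#' @param identity_blocks Block names to pass through unscaled.
#' @return A `channel_scaler`: list with `min`, `max`, `identity`.
#' @export
fit_scaler <- function(x, identity_blocks = "AA") {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  identity <- rep(FALSE, ncol(x))
  if (ncol(x) == sum(FEATURE_BLOCKS) && length(identity_blocks)) {
    sl <- block_slices()
    for (b in identity_blocks) identity[sl[[b]]] <- TRUE
  }
  constant <- mins == maxs
  if (any(constant & !identity)) {
    warning(sum(constant & !identity),
            " constant channel(s) left unscaled")
    identity[constant] <- TRUE
  }
  structure(list(min = mins, max = maxs, identity = identity),
            class = "channel_scaler")
}

#' Apply (or invert) a channel scaler
#'
#' Forward: `x' = 2 (x - min) / (max - min) - 1`, then clipping to
#' `[-1, 1]` for out-of-bounds test-time values. Identity channels pass
#' through. `inverse = TRUE` undoes the map (no clipping).
#'
#' @param scaler A `channel_scaler`.
#' @param x Numeric matrix with one column per channel.
#' @param inverse Invert instead of apply.
#' @param clip Clip forward-scaled values into `[-1, 1]`.
#' @return Matrix of the same shape.
#' @export
apply_scaler <- function(scaler, x, inverse = FALSE, clip = TRUE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  live <- !scaler$identity
  out <- x
  if (any(live)) {
    if (!inverse) {
      out[, live] <- sweep(sweep(x[, live, drop = FALSE], 2,
                                 scaler$min[live]), 2, rng[live], "/") * 2 - 1
      if (clip) out[, live] <- pmin(pmax(out[, live, drop = FALSE], -1), 1)
    } else {
      out[, live] <- sweep(sweep((x[, live, drop = FALSE] + 1) / 2, 2,
                                 rng[live], "*"), 2, scaler$min[live], "+")
    }
  }
  out
}

#' Assemble the full feature matrix
#'
#' Concatenates the seven blocks in the fixed order
#' AA | PP | PSSM | RE | DC | PSSP | RBP (widths 20, 7, 20, 20, 1, 20,
#' 144; total 232), optionally applies a fitted scaler (with clipping),
#' and tags the result with its block layout.
#'
#' @param seq An `esiden_sequence` (supplies AA and, with `pp = NULL`,
#'   the physicochemical block).
#' @param pssm L x 20 PSSM scores.
#' @param re L x 20 relative-entropy block.
#' @param dc Length-L degree-of-conservation vector.
#' @param pssp L x 20 substitution-probability block.
#' @param rbp L x 144 basin-embedding block.
#' @param pp Optional L x 7 physicochemical block (computed from `seq` if
#'   `NULL`).
#' @param scaler Optional `channel_scaler` to apply.
#' @return A `feature_matrix`: numeric L x 232 matrix with attributes
#'   `blocks` (named index slices) and `scaled`.
#' @export
assemble_features <- function(seq, pssm, re, dc, pssp, rbp, pp = NULL,
                              scaler = NULL) {
  aa <- aa_onehot(seq)
  if (is.null(pp)) pp <- physchem_features(seq)
  dc <- matrix(dc, ncol = 1)
  blocks <- list(AA = aa, PP = pp, PSSM = as.matrix(pssm), RE = as.matrix(re),
                 DC = dc, PSSP = as.matrix(pssp), RBP = as.matrix(rbp))
  L <- nrow(aa)
  for (b in names(blocks)) {
    if (nrow(blocks[[b]]) != L) {
      stop("block length mismatch: AA has ", L, " rows but ", b, " has ",
           nrow(blocks[[b]]))
    }
    if (ncol(blocks[[b]]) != FEATURE_BLOCKS[[b]]) {
      stop("block ", b, " must have ", FEATURE_BLOCKS[[b]], " columns, got ",
           ncol(blocks[[b]]))
    }
  }
  x <- do.call(cbind, blocks)
  colnames(x) <- NULL
  scaled <- FALSE
  if (!is.null(scaler)) {
    x <- apply_scaler(scaler, x)
    scaled <- TRUE
  }
  structure(x, blocks = block_slices(), scaled = scaled,
            class = c("feature_matrix", "matrix", "array"))
}

#' Extract one named block from a feature matrix
#'
#' @param features A `feature_matrix`.
#' @param block One of `"AA"`, `"PP"`, `"PSSM"`, `"RE"`, `"DC"`, `"PSSP"`,
#'   `"RBP"`.
#' @return The block's columns as a plain matrix.
#' @export
feature_block <- function(features, block) {
  sl <- attr(features, "blocks")
  if (is.null(sl)) sl <- block_slices()
  if (!block %in% names(sl)) stop("unknown block '", block, "'")
  unclass(features)[, sl[[block]], drop = FALSE]
}

#' Classic-feature matrix (AA | PP | PSSM)
#'
#' The L x 47 concatenation of the three classic blocks.
#'
#' @param seq An `esiden_sequence`.
#' @param pssm L x 20 PSSM scores.
#' @param pp Optional L x 7 physicochemical block.
#' @return An L x 47 numeric matrix.
#' @export
classic_features <- function(seq, pssm, pp = NULL) {
  aa <- aa_onehot(seq)
  if (is.null(pp)) pp <- physchem_features(seq)
  stopifnot(nrow(pssm) == nrow(aa))
  x <- cbind(aa, pp, as.matrix(pssm))
  colnames(x) <- NULL
  x
}
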