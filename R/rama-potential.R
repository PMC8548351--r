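# Triplet-conditioned Ramachandran basin potential: 72x72 (phi, psi)
# probability maps over 5-degree bins, keyed by (left, center, right)
# residue triplets with center-residue backoff, reduced to 72x2 embeddings
# and emitted as the per-residue L x 144 feature block.

RAMA_BINS <- 72L
RAMA_BIN_WIDTH <- 5

# bin index in 1..72 for an angle in [-180, 180); +180 wraps to -180
rama_bin <- function(angle) {
  a <- wrap_angle(angle)
  as.integer(floor((a + 180) / RAMA_BIN_WIDTH)) + 1L
}

triplet_key <- function(left, center, right) paste(left, center, right, sep = "")

#' Build the Ramachandran basin potential from torsion observations
#'
#' Each observation is a residue with its left and right sequence
#' neighbors and its (phi, psi) pair. Angles are binned on a 72 x 72 grid
#' of 5-degree cells (half-open bins, +180 wrapping to -180). One map is
#' accumulated per (left, center, right) triplet and one per center
#' residue (the backoff); triplet maps with fewer than `min_triplet_count`
#' observations are dropped at lookup time in favor of the backoff.
#' `pseudocount` is added to every bin before normalization, so every
#' retained map is a probability distribution.
#'
#' @param records Data frame with columns `left`, `center`, `right`
#'   (one-letter residue codes; terminal neighbors may be `NA` or `"-"`,
#'   such rows still count toward the center map), `phi`, `psi` (degrees).
#' @param pseudocount Per-bin additive count (default 1/5184, one count
#'   spread over the grid).
#' @param min_triplet_count Minimum observations for a triplet map to be
#'   retained (default 20).
#' @return A `basin_potential`: list with `center_maps` (named list of
#'   72 x 72 matrices), `triplet_maps`, `center_counts`, `triplet_counts`,
#'   `bin_width`, `pseudocount`, `min_triplet_count`, `ss_mode = "A"`.
#' @export
build_basin_potential <- function(records, pseudocount = 1 / 5184,
                                  min_triplet_count = 20L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no torsion observations supplied")
  needed <- c("left", "center", "right", "phi", "psi")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "))
  }
  bi <- rama_bin(records$phi)
  bj <- rama_bin(records$psi)
  center <- as.character(records$center)
  left <- as.character(records$left)
  right <- as.character(records$right)
  left[is.na(left)] <- "-"
  right[is.na(right)] <- "-"

  center_counts <- new.env(parent = emptyenv())
  triplet_counts <- new.env(parent = emptyenv())
  add_obs <- function(env, key, i, j) {
    m <- get0(key, envir = env)
    if (is.null(m)) m <- matrix(0, RAMA_BINS, RAMA_BINS)
    m[i, j] <- m[i, j] + 1
    assign(key, m, envir = env)
  }
  has_triplet <- left != "-" & right != "-"
  for (k in seq_len(nrow(records))) {
    add_obs(center_counts, center[[k]], bi[[k]], bj[[k]])
    if (has_triplet[[k]]) {
      add_obs(triplet_counts, triplet_key(left[[k]], center[[k]], right[[k]]),
              bi[[k]], bj[[k]])
    }
  }
  normalize <- function(m) {
    m <- m + pseudocount
    m / sum(m)
  }
  ckeys <- ls(center_counts)
  if (pseudocount > 0) {
    # with smoothing, every standard residue gets a (possibly uniform)
    # backoff map so downstream lookups never fail
    for (a in setdiff(AA_ALPHABET, ckeys)) {
      assign(a, matrix(0, RAMA_BINS, RAMA_BINS), envir = center_counts)
    }
    ckeys <- ls(center_counts)
  }
  tkeys <- ls(triplet_counts)
  tcounts <- vapply(tkeys, function(k) sum(get(k, envir = triplet_counts)),
                    numeric(1))
  keep <- tkeys[tcounts >= min_triplet_count]
  structure(list(
    center_maps = stats::setNames(
      lapply(ckeys, function(k) normalize(get(k, envir = center_counts))), ckeys),
    triplet_maps = stats::setNames(
      lapply(keep, function(k) normalize(get(k, envir = triplet_counts))), keep),
    center_counts = stats::setNames(
      vapply(ckeys, function(k) sum(get(k, envir = center_counts)), numeric(1)),
      ckeys),
    triplet_counts = stats::setNames(tcounts, tkeys),
    bin_width = RAMA_BIN_WIDTH,
    pseudocount = pseudocount,
    min_triplet_count = as.integer(min_triplet_count),
    ss_mode = "A"
  ), class = "basin_potential")
}

#' @export
print.basin_potential <- function(x, ...) {
  cat(sprintf(
    "<basin_potential> %d center maps, %d retained triplet maps (5-degree bins)\n",
    length(x$center_maps), length(x$triplet_maps)))
  invisible(x)
}

#' Collect triplet torsion observations from chains
#'
#' Turns (chain, torsions) pairs into the observation table that
#' [build_basin_potential()] consumes: one row per residue with both
#' angles valid, keyed by its left/right sequence neighbors.
#'
#' @param chains List of `backbone_chain` objects (or objects with an `aa`
#'   column in `$residues`).
#' @param torsions List of matching `torsion_series`.
#' @return A tibble with columns `left`, `center`, `right`, `phi`, `psi`.
#' @export
collect_torsion_records <- function(chains, torsions) {
  stopifnot(length(chains) == length(torsions))
  out <- vector("list", length(chains))
  for (c in seq_along(chains)) {
    aa <- chains[[c]]$residues$aa
    ts <- torsions[[c]]
    ok <- ts$phi_mask & ts$psi_mask
    idx <- which(ok)
    if (length(idx) == 0L) next
    left <- ifelse(idx > 1L, aa[pmax(idx - 1L, 1L)], "-")
    right <- ifelse(idx < length(aa), aa[pmin(idx + 1L, length(aa))], "-")
    out[[c]] <- tibble::tibble(left = left, center = aa[idx], right = right,
                               phi = ts$phi[idx], psi = ts$psi[idx])
  }
  dplyr::bind_rows(out)
}

#' Reduce basin maps to 72 x 2 embeddings
#'
#' Each 72 x 72 map is treated as 72 points (the phi rows) in the
#' 72-dimensional psi space and embedded to 2 dimensions, giving a 72 x 2
#' matrix per key. `"pca"` uses the first two principal components with a
#' deterministic sign convention; `"tsne"` uses the package's exact t-SNE
#' with the given seed. Identical seeds and inputs give identical
#' embeddings.
#'
#' @param potential A `basin_potential`.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed recorded in (and controlling) the reduction.
#' @param perplexity t-SNE perplexity (ignored for PCA).
#' @return A `reduced_basin_set`: list with `embeddings` (named list of
#'   72 x 2 matrices, center keys and retained triplet keys), `method`,
#'   `seed`.
#' @export
reduce_basins <- function(potential, method = c("pca", "tsne"), seed = 1L,
                          perplexity = 15) {
  method <- match.arg(method)
  maps <- c(potential$center_maps, potential$triplet_maps)
  embed_one <- function(m) {
    if (method == "pca") {
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      k <- min(2L, ncol(pc$x))
      y <- matrix(0, RAMA_BINS, 2)
      y[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
      # sign convention: largest-magnitude loading of each PC is positive
      for (j in seq_len(k)) {
        rot <- pc$rotation[, j]
        if (rot[which.max(abs(rot))] < 0) y[, j] <- -y[, j]
      }
      y
    } else {
      tsne_embed(m, dims = 2L, perplexity = perplexity, seed = seed)
    }
  }
  structure(list(embeddings = lapply(maps, embed_one),
                 method = method, seed = as.integer(seed)),
            class = "reduced_basin_set")
}

#' @export
print.reduced_basin_set <- function(x, ...) {
  cat(sprintf("<reduced_basin_set> %d embeddings (method %s, seed %d)\n",
              length(x$embeddings), x$method, x$seed))
  invisible(x)
}

#' Per-residue Ramachandran basin feature block
#'
#' Residue i is keyed by the triplet (seq[i-1], seq[i], seq[i+1]); terminal
#' residues and triplets without a retained map fall back to the center
#' residue's map. The residue's 72 x 2 embedding is flattened row-major
#' into 144 values.
#'
#' @param seq An `esiden_sequence`.
#' @param reduced A `reduced_basin_set` whose embeddings cover at least the
#'   center keys appearing in `seq`.
#' @return An L x 144 numeric matrix.
#' @export
rbp_features <- function(seq, reduced) {
  chars <- seq_chars(seq)
  L <- length(chars)
  out <- matrix(0, L, 2L * RAMA_BINS)
  for (i in seq_len(L)) {
    key <- NULL
    if (i > 1L && i < L) {
      tk <- triplet_key(chars[i - 1L], chars[i], chars[i + 1L])
      if (tk %in% names(reduced$embeddings)) key <- tk
    }
    if (is.null(key)) key <- chars[i]
    emb <- reduced$embeddings[[key]]
    if (is.null(emb)) {
      stop("no basin embedding for residue '", chars[i], "' at position ", i)
    }
    out[i, ] <- as.vector(t(emb))  # row-major flatten
  }
  out
}

#' Serialize a basin potential (with optional reduction) to JSON
#'
#' @param potential A `basin_potential`.
#' @param path Output path.
#' @param reduced Optional `reduced_basin_set` stored alongside.
#' @return `path`, invisibly.
#' @export
write_basin_potential <- function(potential, path, reduced = NULL) {
  payload <- list(
    version = 1L,
    bin_width = potential$bin_width,
    pseudocount = potential$pseudocount,
    min_triplet_count = potential$min_triplet_count,
    ss_mode = potential$ss_mode,
    center_maps = potential$center_maps,
    triplet_maps = potential$triplet_maps,
    center_counts = as.list(potential$center_counts),
    triplet_counts = as.list(potential$triplet_counts)
  )
  if (!is.null(reduced)) {
    payload$reduction <- list(method = reduced$method, seed = reduced$seed,
                              embeddings = reduced$embeddings)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a basin potential serialized by [write_basin_potential()]
#'
#' @param path Input path.
#' @return A list with `potential` (`basin_potential`) and `reduced`
#'   (`reduced_basin_set` or `NULL`).
#' @export
read_basin_potential <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_map <- function(x) matrix(unlist(x), RAMA_BINS, RAMA_BINS)
  relist_maps <- function(maps) {
    if (length(maps) == 0L) return(stats::setNames(list(), character()))
    lapply(maps, function(m) if (is.matrix(m)) m else as_map(m))
  }
  potential <- structure(list(
    center_maps = relist_maps(p$center_maps),
    triplet_maps = relist_maps(p$triplet_maps),
    center_counts = unlist(p$center_counts),
    triplet_counts = unlist(p$triplet_counts),
    bin_width = p$bin_width,
    pseudocount = p$pseudocount,
    min_triplet_count = p$min_triplet_count,
    ss_mode = p$ss_mode
  ), class = "basin_potential")
  reduced <- NULL
  if (!is.null(p$reduction)) {
    emb <- lapply(p$reduction$embeddings, function(m) {
      if (is.matrix(m)) m else matrix(unlist(m), RAMA_BINS, 2L)
    })
    reduced <- structure(list(embeddings = emb, method = p$reduction$method,
                              seed = as.integer(p$reduction$seed)),
                         class = "reduced_basin_set")
  }
  list(potential = potential, reduced = reduced)
}
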