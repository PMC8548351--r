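# Evolutionary-signature features computed from an MSA: relative entropy
# (RE), degree of conservation (DC), and position-specific substitution
# probabilities (PSSP) from independent-site Potts fields.

#' Trim an alignment by per-row gap fraction
#'
#' Rows whose gap fraction over the query columns exceeds
#' `max_row_gap_fraction` are removed; the query row is always retained.
#'
#' @param msa An `aligned_msa`.
#' @param max_row_gap_fraction Maximum tolerated gap fraction in (0, 1].
#' @return The trimmed `aligned_msa`.
#' @export
trim_msa <- function(msa, max_row_gap_fraction = 0.5) {
  stopifnot(max_row_gap_fraction > 0, max_row_gap_fraction <= 1)
  gapfrac <- vapply(msa$rows, function(r) {
    chars <- strsplit(r, "")[[1]]
    mean(chars == "-")
  }, numeric(1), USE.NAMES = FALSE)
  keep <- gapfrac <= max_row_gap_fraction
  keep[1] <- TRUE
  structure(list(query = msa$query, rows = msa$rows[keep],
                 ids = msa$ids[keep]), class = "aligned_msa")
}

#' Per-column amino-acid frequencies of an alignment
#'
#' Gaps are excluded and the remaining counts, plus `pseudocount` per amino
#' acid, are renormalized so each column's frequencies sum to 1. The
#' background distribution is either the packaged standard table
#' ([aa_background()]) or the pooled non-gap frequencies of the MSA itself.
#'
#' @param msa An `aligned_msa`.
#' @param background_mode `"fixed_table"` or `"pooled"`.
#' @param pseudocount Additive smoothing count per amino acid (>= 0).
#' @return A `column_profile`: list with `freqs` (L x 20, canonical
#'   alphabetical column order), `background` (length 20) and
#'   `effective_depth` (non-gap count per column).
#' @export
column_frequencies <- function(msa, background_mode = c("fixed_table", "pooled"),
                               pseudocount = 0) {
  background_mode <- match.arg(background_mode)
  stopifnot(pseudocount >= 0)
  m <- msa_matrix(msa)
  L <- ncol(m)
  counts <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (a in seq_along(AA_ALPHABET)) {
    counts[, a] <- colSums(m == AA_ALPHABET[[a]])
  }
  depth <- rowSums(counts)  # non-gap, non-X mass per column
  if (pseudocount == 0 && any(depth == 0)) {
    stop("column ", which(depth == 0)[1],
         " has no non-gap residues and pseudocount is 0")
  }
  freqs <- (counts + pseudocount) / (depth + 20 * pseudocount)
  background <- switch(background_mode,
    fixed_table = aa_background(),
    pooled = {
      tot <- colSums(counts)
      if (sum(tot) == 0) stop("cannot pool background from an all-gap MSA")
      # keep strictly positive: smooth with a single count spread uniformly
      tot <- tot + 1 / 20
      tot / sum(tot)
    })
  structure(list(freqs = freqs, background = background,
                 effective_depth = depth),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> %d columns, mean depth %.1f\n",
              nrow(x$freqs), mean(x$effective_depth)))
  invisible(x)
}

#' Relative entropy of each amino acid at each position
#'
#' For each column i and amino acid a, the binary Kullback-Leibler
#' divergence between the observed frequency f and the background p:
#' `RE = f*ln(f/p) + (1-f)*ln((1-f)/(1-p))`, with the standard convention
#' `0*ln(0/q) = 0`. Nonnegative, zero exactly when f = p.
#'
#' @param profile A `column_profile`.
#' @return An L x 20 numeric matrix (canonical alphabetical column order).
#' @export
relative_entropy <- function(profile) {
  f <- profile$freqs
  p <- profile$background
  if (any(p <= 0) || any(p >= 1)) {
    stop("background probabilities must lie strictly inside (0, 1)")
  }
  pm <- matrix(p, nrow(f), 20, byrow = TRUE)
  term1 <- ifelse(f > 0, f * log(f / pm), 0)
  term2 <- ifelse(f < 1, (1 - f) * log((1 - f) / (1 - pm)), 0)
  re <- term1 + term2
  # clamp tiny negative round-off at f ~= p
  re[re < 0 & re > -1e-12] <- 0
  dimnames(re) <- dimnames(f)
  re
}

#' Degree of conservation per position
#'
#' The row sum of the relative-entropy matrix: an L-vector summarizing how
#' far each column's composition departs from background.
#'
#' @param re An L x 20 relative-entropy matrix from [relative_entropy()].
#' @return Numeric vector of length L.
#' @export
degree_of_conservation <- function(re) {
  rowSums(re)
}

#' Fit independent-site Potts fields to a column profile
#'
#' With pairwise couplings ignored, the maximum-likelihood site fields of
#' the evolutionary statistical energy have the closed form
#' `h_i(a) = ln f~_i(a) - mean_a ln f~_i(a)`, where `f~` are the
#' `pseudocount`-smoothed column frequencies. Each row is gauge-fixed to
#' sum to zero, and `softmax(h_i)` reproduces `f~_i` exactly.
#'
#' @param profile A `column_profile`.
#' @param pseudocount Additional smoothing applied on top of the profile's
#'   frequencies, as a probability mass mixed uniformly (default 0; the
#'   smoothed frequencies must be strictly positive).
#' @return A `site_fields`: list with `h` (L x 20, rows summing to 0) and
#'   `pseudocount`.
#' @export
fit_site_fields <- function(profile, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  f <- profile$freqs
  if (pseudocount > 0) {
    depth <- pmax(profile$effective_depth, 1)
    f <- (f * depth + pseudocount) / (depth + 20 * pseudocount)
  }
  if (any(f <= 0)) {
    stop("smoothed frequencies must be strictly positive; ",
         "increase the pseudocount")
  }
  lf <- log(f)
  h <- lf - rowMeans(lf)
  dimnames(h) <- dimnames(f)
  structure(list(h = h, pseudocount = pseudocount), class = "site_fields")
}

#' @export
print.site_fields <- function(x, ...) {
  cat(sprintf("<site_fields> %d positions (pseudocount %g)\n",
              nrow(x$h), x$pseudocount))
  invisible(x)
}

#' Position-specific substitution probabilities from site fields
#'
#' The per-row softmax of the site biases: each row is a probability
#' distribution over the 20 amino acids.
#'
#' @param fields A `site_fields` object.
#' @return An L x 20 matrix with rows summing to 1.
#' @export
pssp_from_fields <- function(fields) {
  h <- fields$h
  m <- apply(h, 1, max)
  e <- exp(h - m)
  p <- e / rowSums(e)
  dimnames(p) <- dimnames(h)
  p
}

#' Compute all MSA-derived evolutionary features at once
#'
#' Convenience wrapper: trims the alignment, builds the column profile, and
#' returns RE, DC and PSSP together.
#'
#' @param msa An `aligned_msa`.
#' @param background_mode Passed to [column_frequencies()].
#' @param pseudocount Pseudocount for both the profile and the site fields.
#' @param max_row_gap_fraction Passed to [trim_msa()].
#' @return List with `re` (L x 20), `dc` (L), `pssp` (L x 20) and the
#'   intermediate `profile`.
#' @export
evolutionary_features <- function(msa, background_mode = "fixed_table",
                                  pseudocount = 1,
                                  max_row_gap_fraction = 0.5) {
  msa <- trim_msa(msa, max_row_gap_fraction)
  profile <- column_frequencies(msa, background_mode, pseudocount)
  re <- relative_entropy(profile)
  dc <- degree_of_conservation(re)
  fields <- fit_site_fields(profile)
  pssp <- pssp_from_fields(fields)
  list(re = re, dc = dc, pssp = pssp, profile = profile)
}
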