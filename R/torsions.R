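# Torsion-series container and dihedral geometry.

#' Construct a torsion series
#'
#' A per-residue table of backbone torsion angles in degrees with validity
#' masks. By convention phi is undefined at the first residue and psi at
#' the last; masked entries carry a 0 sentinel and are excluded from all
#' statistics.
#'
#' @param phi,psi Numeric vectors of angles in degrees, in `[-180, 180)`.
#' @param phi_mask,psi_mask Logical vectors; `TRUE` marks a valid angle.
#' @param aa Optional residue letters.
#' @return A `torsion_series` tibble with columns `resi`, `aa`, `phi`,
#'   `psi`, `phi_mask`, `psi_mask`.
#' @export
new_torsion_series <- function(phi, psi, phi_mask = NULL, psi_mask = NULL,
                               aa = NULL) {
  L <- length(phi)
  stopifnot(length(psi) == L)
  if (is.null(phi_mask)) phi_mask <- c(FALSE, rep(TRUE, L - 1L))
  if (is.null(psi_mask)) psi_mask <- c(rep(TRUE, L - 1L), FALSE)
  stopifnot(length(phi_mask) == L, length(psi_mask) == L)
  if (is.null(aa)) aa <- rep("X", L)
  phi <- ifelse(phi_mask, wrap_angle(phi), 0)
  psi <- ifelse(psi_mask, wrap_angle(psi), 0)
  out <- tibble::tibble(resi = seq_len(L), aa = aa, phi = phi, psi = psi,
                        phi_mask = phi_mask, psi_mask = psi_mask)
  class(out) <- c("torsion_series", class(out))
  out
}

# Wrap degrees into [-180, 180).
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Signed dihedral angle of four points
#'
#' The IUPAC-signed torsion about the p2-p3 axis, computed with the
#' quadrant-aware two-argument arctangent, in degrees in `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12) {
    stop("degenerate geometry: coincident consecutive points")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("degenerate geometry: parallel consecutive bond vectors")
  }
  b2h <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2h)
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract backbone torsions from a chain
#'
#' phi_i is the dihedral of C_(i-1), N_i, CA_i, C_i and psi_i that of N_i,
#' CA_i, C_i, N_(i+1). The first phi and last psi are masked, as are all
#' angles that involve an incomplete residue or span a chain break (a
#' C_i to N_(i+1) peptide-bond distance above `break_threshold`).
#'
#' @param chain A `backbone_chain`.
#' @param break_threshold Chain-break distance cutoff in Angstrom.
#' @return A `torsion_series` tibble.
#' @export
extract_torsions <- function(chain, break_threshold = 2.0) {
  L <- length(chain)
  complete <- chain$residues$complete
  if (sum(complete) < 2L) stop("need at least 2 complete residues")
  phi <- numeric(L)
  psi <- numeric(L)
  phi_mask <- logical(L)
  psi_mask <- logical(L)
  bonded <- logical(max(L - 1L, 0L))  # C_i -- N_{i+1} intact
  for (i in seq_len(L - 1L)) {
    if (complete[i] && complete[i + 1L]) {
      d <- sqrt(sum((chain$coords[[i + 1L]]["N", ] -
                     chain$coords[[i]]["C", ])^2))
      bonded[i] <- d <= break_threshold
    }
  }
  for (i in seq_len(L)) {
    if (i > 1L && complete[i] && complete[i - 1L] && bonded[i - 1L]) {
      phi[i] <- dihedral_angle(chain$coords[[i - 1L]]["C", ],
                               chain$coords[[i]]["N", ],
                               chain$coords[[i]]["CA", ],
                               chain$coords[[i]]["C", ])
      phi_mask[i] <- TRUE
    }
    if (i < L && complete[i] && complete[i + 1L] && bonded[i]) {
      psi[i] <- dihedral_angle(chain$coords[[i]]["N", ],
                               chain$coords[[i]]["CA", ],
                               chain$coords[[i]]["C", ],
                               chain$coords[[i + 1L]]["N", ])
      psi_mask[i] <- TRUE
    }
  }
  new_torsion_series(phi, psi, phi_mask, psi_mask, aa = chain$residues$aa)
}
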