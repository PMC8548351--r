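# Readers/writers for FASTA, aligned MSA/A3M, PDB backbones and PSI-BLAST
# ASCII PSSM files, plus the TSV angle-table format used by the CLI.

#' Read sequences from a FASTA file
#'
#' Records are parsed with [Biostrings::readBStringSet()]; wrapped lines are
#' concatenated and identifiers are taken from the header up to the first
#' whitespace. Residues outside the 20 standard one-letter codes are
#' canonicalized to `'X'`.
#'
#' @param path Path to a FASTA file.
#' @return A list of `esiden_sequence` objects (fields `id`, `residues`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error in '", path, "': no records")
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(seqs), function(i) {
    new_sequence(ids[[i]], seqs[[i]])
  })
  out
}

new_sequence <- function(id, residues) {
  residues <- canonicalize_residues(residues)
  if (nchar(residues) == 0L) stop("empty sequence for record '", id, "'")
  structure(list(id = id, residues = residues), class = "esiden_sequence")
}

#' @export
print.esiden_sequence <- function(x, ...) {
  cat(sprintf("<sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
length.esiden_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Write sequences to FASTA
#'
#' @param seqs A list of `esiden_sequence` objects (or one such object).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "esiden_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    r <- s$residues
    starts <- seq(1L, nchar(r), by = width)
    writeLines(substring(r, starts, pmin(starts + width - 1L, nchar(r))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' The first record is the query. For `format = "a3m"` lowercase insertion
#' characters are removed so every row is projected onto the query's match
#' columns; `'.'` gap characters are normalized to `'-'`. After projection
#' every row must have the query's length.
#'
#' @param path Path to an aligned FASTA or A3M file.
#' @param format `"afa"` (aligned FASTA) or `"a3m"`.
#' @return An `aligned_msa` object with fields `query` (an
#'   `esiden_sequence`) and `rows` (character vector of gapped strings,
#'   row 1 being the query).
#' @export
read_msa <- function(path, format = c("afa", "a3m")) {
  format <- match.arg(format)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("MSA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("MSA format error in '", path, "': no records")
  rows <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (format == "a3m") {
    rows <- vapply(rows, function(r) gsub("[a-z]", "", r), character(1),
                   USE.NAMES = FALSE)
  }
  rows <- gsub("\\.", "-", rows)
  rows <- toupper(rows)
  new_aligned_msa(rows, ids = ids, source = path)
}

new_aligned_msa <- function(rows, ids = NULL, source = NULL) {
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("MSA format error", if (!is.null(source)) paste0(" in '", source, "'"),
         ": rows of unequal projected length (", paste(unique(lens), collapse = ", "), ")")
  }
  query_row <- rows[[1]]
  if (grepl("-", query_row, fixed = TRUE)) {
    # project all rows onto the query's non-gap columns
    keep <- which(strsplit(query_row, "")[[1]] != "-")
    rows <- vapply(rows, function(r) {
      paste(strsplit(r, "")[[1]][keep], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (is.null(ids)) ids <- c("query", paste0("row", seq_along(rows)[-1]))
  query <- new_sequence(ids[[1]], rows[[1]])
  structure(list(query = query, rows = rows, ids = ids),
            class = "aligned_msa")
}

#' @export
print.aligned_msa <- function(x, ...) {
  cat(sprintf("<aligned_msa> %d rows x %d columns (query: %s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$query$id))
  invisible(x)
}

#' @export
dim.aligned_msa <- function(x) c(length(x$rows), nchar(x$rows[[1]]))

#' Write an alignment as aligned FASTA
#'
#' @param msa An `aligned_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$rows)) {
    writeLines(c(paste0(">", msa$ids[[i]]), msa$rows[[i]]), con)
  }
  invisible(path)
}

# MSA rows as an L-column character matrix (one residue per cell).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Read backbone atoms of one chain from a PDB file
#'
#' ATOM records are parsed with [bio3d::read.pdb()]; only the N, CA and C
#' atoms of the requested chain are kept (first model of multi-model
#' files). When a residue carries alternate locations, the altloc with the
#' highest occupancy wins, ties broken by altloc label order. Nonstandard
#' residues are mapped to one-letter codes (MSE to M, unknowns to X).
#' Residues missing any of N/CA/C are flagged incomplete.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single character).
#' @return A `backbone_chain`: list with `chain_id`, `residues` (a tibble
#'   with columns `resi` (1-based contiguous), `author_resi`, `aa`,
#'   `complete`) and `coords`, a list of 3x3 matrices (rows N, CA, C).
#' @export
read_pdb_backbone <- function(path, chain) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain '", chain, "' not found in '", path, "'")
  atoms <- atoms[atoms$elety %in% c("N", "CA", "C"), , drop = FALSE]
  # residue identity: author number + insertion code
  ins <- if ("insert" %in% names(atoms)) {
    ifelse(is.na(atoms$insert), "", atoms$insert)
  } else ""
  rid <- paste0(atoms$resno, ins)
  resid_order <- unique(rid)
  alt <- if ("alt" %in% names(atoms)) ifelse(is.na(atoms$alt), "", atoms$alt) else ""
  occ <- if ("o" %in% names(atoms)) ifelse(is.na(atoms$o), 1, atoms$o) else 1

  n <- length(resid_order)
  coords <- vector("list", n)
  aa <- character(n)
  complete <- logical(n)
  author <- character(n)
  for (k in seq_len(n)) {
    sel <- which(rid == resid_order[[k]])
    sub <- atoms[sel, , drop = FALSE]
    author[[k]] <- resid_order[[k]]
    aa3 <- sub$resid[[1]]
    aa[[k]] <- if (aa3 %in% names(AA3_TO_1)) AA3_TO_1[[aa3]] else "X"
    m <- matrix(NA_real_, 3, 3, dimnames = list(c("N", "CA", "C"),
                                                c("x", "y", "z")))
    for (atom in c("N", "CA", "C")) {
      i <- sel[sub$elety == atom]
      if (length(i) == 0L) next
      if (length(i) > 1L) {
        # highest occupancy, ties by altloc label order
        o <- occ[i]
        a <- alt[i]
        i <- i[order(-o, a)][1]
      }
      m[atom, ] <- c(atoms$x[[i]], atoms$y[[i]], atoms$z[[i]])
    }
    coords[[k]] <- m
    complete[[k]] <- !anyNA(m)
  }
  new_backbone_chain(chain_id = chain, aa = aa, coords = coords,
                     complete = complete, author_resi = author)
}

new_backbone_chain <- function(chain_id, aa, coords, complete,
                               author_resi = as.character(seq_along(aa))) {
  structure(list(
    chain_id = chain_id,
    residues = tibble::tibble(resi = seq_along(aa), author_resi = author_resi,
                              aa = aa, complete = complete),
    coords = coords
  ), class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> %s: %d residues (%d complete)\n",
              x$chain_id, nrow(x$residues), sum(x$residues$complete)))
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) nrow(x$residues)

#' Write a backbone chain as a minimal PDB file
#'
#' Emits ATOM records for the N, CA and C atoms of complete residues;
#' useful for round-tripping synthetic backbones through PDB tools.
#'
#' @param chain A `backbone_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_backbone <- function(chain, path) {
  one_to_three <- names(AA3_TO_1)[match(chain$residues$aa, AA3_TO_1)]
  one_to_three[is.na(one_to_three)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (k in seq_len(nrow(chain$residues))) {
    m <- chain$coords[[k]]
    for (atom in c("N", "CA", "C")) {
      if (anyNA(m[atom, ])) next
      serial <- serial + 1L
      elem <- substr(atom, 1, 1)
      writeLines(sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", atom), " ", one_to_three[[k]], chain$chain_id,
        chain$residues$resi[[k]], " ",
        m[atom, "x"], m[atom, "y"], m[atom, "z"], 1.00, 0.00, elem), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard `-out_ascii_pssm` layout: a header, then one row per
#' residue whose first 22 fields are position, residue letter, and the 20
#' log-odds scores in the fixed PSI-BLAST amino-acid order.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A `pssm_profile`: list with `query` (`esiden_sequence`) and
#'   `scores`, an L x 20 integer matrix with PSI-BLAST-ordered colnames.
#' @export
read_psiblast_pssm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("PSSM format error in '", path, "': empty file")
  # data rows start with an integer position followed by a residue letter
  is_data <- grepl("^\\s*\\d+\\s+[A-Za-z]\\s", lines)
  rows <- lines[is_data]
  if (length(rows) == 0L) {
    stop("PSSM format error in '", path, "': no data rows found")
  }
  scores <- matrix(0L, length(rows), 20L,
                   dimnames = list(NULL, PSSM_ORDER))
  letters_seen <- character(length(rows))
  for (i in seq_along(rows)) {
    toks <- strsplit(trimws(rows[[i]]), "\\s+")[[1]]
    if (length(toks) < 22L) {
      stop("PSSM format error in '", path, "': truncated row at position ",
           toks[1])
    }
    pos <- suppressWarnings(as.integer(toks[[1]]))
    if (is.na(pos) || pos != i) {
      stop("PSSM format error in '", path, "': unexpected position field '",
           toks[[1]], "' at data row ", i)
    }
    letters_seen[[i]] <- toks[[2]]
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(vals)) {
      stop("PSSM format error in '", path, "': non-integer score at position ",
           pos)
    }
    scores[i, ] <- vals
  }
  query <- new_sequence("pssm_query", paste(letters_seen, collapse = ""))
  structure(list(query = query, scores = scores), class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %d positions x 20 scores\n", nrow(x$scores)))
  invisible(x)
}

#' Write a torsion series as TSV
#'
#' Columns: `resi`, `aa`, `phi`, `psi`, `phi_mask`, `psi_mask`. Masked
#' angles are written as `NA`.
#'
#' @param torsions A `torsion_series` tibble (see [extract_torsions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_torsion_tsv <- function(torsions, path) {
  df <- as.data.frame(torsions)
  df$phi[!df$phi_mask] <- NA_real_
  df$psi[!df$psi_mask] <- NA_real_
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a torsion-series TSV written by [write_torsion_tsv()]
#'
#' @param path Input path.
#' @return A `torsion_series` tibble.
#' @export
read_torsion_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  phi <- df$phi
  psi <- df$psi
  phi_mask <- as.logical(df$phi_mask) & !is.na(phi)
  psi_mask <- as.logical(df$psi_mask) & !is.na(psi)
  phi[is.na(phi)] <- 0
  psi[is.na(psi)] <- 0
  new_torsion_series(phi, psi, phi_mask, psi_mask,
                     aa = if ("aa" %in% names(df)) df$aa else NULL)
}
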