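#' Construct a multiple sequence alignment object
#'
#' An alignment is stored as a character matrix (rows = taxa, columns =
#' sites, IUPAC nucleotide codes, upper case) with a recorded reading frame.
#' The codon position of column `i` is `((i - 1 - frame_offset) %% 3) + 1`
#' for columns past the frame offset.
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix with one row per taxon (rownames = taxon ids).
#' @param frame_offset 0-based column index at which codon position 1 starts.
#' @return An object of class `rh1_alignment` (a character matrix with
#'   attributes `frame_offset`).
#' @export
new_alignment <- function(seqs, frame_offset = 0L) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  } else if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    if (is.null(rownames(mat))) stop("alignment matrix must have rownames")
  } else {
    stop("seqs must be a named character vector or character matrix")
  }
  bad <- setdiff(unique(as.vector(mat)), names(.iupac_states))
  if (length(bad) > 0) {
    stop("alignment contains non-IUPAC characters: ", paste(bad, collapse = " "))
  }
  if (frame_offset < 0 || frame_offset >= max(1L, ncol(mat))) {
    stop("frame_offset out of range")
  }
  structure(mat, frame_offset = as.integer(frame_offset),
            class = c("rh1_alignment", "matrix", "array"))
}

#' @export
print.rh1_alignment <- function(x, ...) {
  cat(sprintf("rh1_alignment: %d taxa x %d columns (frame offset %d)\n",
              nrow(x), ncol(x), attr(x, "frame_offset")))
  invisible(x)
}

#' Codon position of each alignment column
#'
#' @param aln An `rh1_alignment`.
#' @return Integer vector in `{1,2,3}` (columns before the frame offset get
#'   `NA`).
#' @export
codon_positions <- function(aln) {
  off <- attr(aln, "frame_offset") %||% 0L
  idx <- seq_len(ncol(aln)) - 1L - off
  pos <- (idx %% 3L) + 1L
  pos[idx < 0L] <- NA_integer_
  pos
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped); sequences must be aligned
#'   (equal length).
#' @param frame_offset Reading frame offset, see [new_alignment()].
#' @return An `rh1_alignment`.
#' @export
read_fasta_alignment <- function(path, frame_offset = 0L) {
  mat <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  new_alignment(toupper(mat), frame_offset = frame_offset)
}

#' Write an alignment to FASTA
#'
#' @param aln An `rh1_alignment`.
#' @param path Output file.
#' @param wrap Line width for sequence lines (`Inf` for single-line records).
#' @export
write_fasta_alignment <- function(aln, path, wrap = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    if (is.finite(wrap) && nchar(s) > wrap) {
      starts <- seq(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Per-taxon base counts at one codon position
#'
#' Ambiguity codes and gaps are excluded from the counts.
#'
#' @param aln An `rh1_alignment`.
#' @param codon_position 1, 2 or 3.
#' @return Integer matrix (taxa x 4 bases).
#' @export
composition_base_counts <- function(aln, codon_position) {
  stopifnot(codon_position %in% 1:3)
  cols <- which(codon_positions(aln) == codon_position)
  counts <- matrix(0L, nrow = nrow(aln), ncol = 4L,
                   dimnames = list(rownames(aln), .nuc_letters))
  sub <- aln[, cols, drop = FALSE]
  for (b in seq_along(.nuc_letters)) {
    counts[, b] <- rowSums(sub == .nuc_letters[b])
  }
  counts
}

#' Chi-squared test of base-composition homogeneity across taxa
#'
#' Classical contingency-style homogeneity test on the taxa x 4 base-count
#' table at one codon position: expected counts come from the pooled marginal
#' base frequencies, the statistic is `sum((O-E)^2 / E)` over cells with
#' positive expectation, and the degrees of freedom follow the 4-base
#' convention `(n_taxa - 1) * 3` (bases entirely absent from the data still
#' count towards df). Taxa with no countable base at the position are dropped
#' with a warning.
#'
#' @param aln An `rh1_alignment`.
#' @param codon_position 1, 2 or 3.
#' @return An object of class `rh1_comp_test` with elements `counts`,
#'   `statistic`, `df`, `p_value`, `codon_position`, `dropped_taxa`.
#' @export
composition_homogeneity_test <- function(aln, codon_position) {
  counts <- composition_base_counts(aln, codon_position)
  empty <- rowSums(counts) == 0L
  dropped <- rownames(counts)[empty]
  if (length(dropped) > 0) {
    warning("dropping taxa with no countable bases at position ",
            codon_position, ": ", paste(dropped, collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2L) stop("need at least 2 taxa with countable bases")
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  expected <- outer(row_tot, col_tot) / sum(counts)
  use <- expected > 0
  stat <- sum((counts[use] - expected[use])^2 / expected[use])
  df <- (nrow(counts) - 1L) * 3L
  structure(
    list(counts = counts, statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         codon_position = codon_position, dropped_taxa = dropped),
    class = "rh1_comp_test")
}

#' @export
print.rh1_comp_test <- function(x, ...) {
  cat(sprintf(
    "Base composition homogeneity, codon position %d: X2 = %.4f, df = %d, p = %.4g\n",
    x$codon_position, x$statistic, x$df, x$p_value))
  invisible(x)
}

# RY projection of every IUPAC code: codes wholly within {A,G} -> R, wholly
# within {C,T} -> Y, codes spanning both purines and pyrimidines -> N.
.ry_map <- c(A = "R", G = "R", R = "R",
             C = "Y", T = "Y", U = "Y", Y = "Y",
             K = "N", M = "N", S = "N", W = "N",
             B = "N", D = "N", H = "N", V = "N", N = "N",
             `-` = "-", `?` = "N")

#' RY-recode selected codon positions
#'
#' Recodes purines (A, G) as R and pyrimidines (C, T) as Y at the selected
#' codon positions (third position by default), suppressing base-composition
#' signal while retaining transversion information. Ambiguity codes map to
#' their purine/pyrimidine projection (codes spanning both classes become N);
#' gaps are untouched. The transform is idempotent.
#'
#' @param aln An `rh1_alignment`.
#' @param positions Codon positions to recode (subset of 1:3).
#' @return The recoded `rh1_alignment`.
#' @export
ry_recode <- function(aln, positions = 3L) {
  stopifnot(all(positions %in% 1:3))
  cols <- which(codon_positions(aln) %in% positions)
  out <- unclass(aln)
  out[, cols] <- .ry_map[out[, cols]]
  new_alignment(out, frame_offset = attr(aln, "frame_offset"))
}
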