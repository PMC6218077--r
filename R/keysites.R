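#' Spectral-tuning key sites in bovine rhodopsin numbering
#'
#' The twelve amino-acid positions whose replacements shift the wavelength
#' of maximal absorption of vertebrate rhodopsins, plus site 210, which
#' separates the "deep-sea" and "freshwater" rhodopsin types (V vs C) in
#' eels.
#'
#' @return List with `key_sites` (the 12 positions) and `extra_sites` (210).
#' @export
key_site_table <- function() {
  list(key_sites = c(83L, 96L, 102L, 122L, 183L, 194L, 195L,
                     253L, 261L, 289L, 292L, 317L),
       extra_sites = 210L)
}

#' Packaged bovine rhodopsin reference
#'
#' The 348-residue Bos taurus rod opsin protein (UniProt P02699), the
#' coordinate reference for rhodopsin site numbering.
#'
#' @return A `Biostrings::AAString`.
#' @export
bovine_rhodopsin <- function() {
  fa <- Biostrings::readAAStringSet(
    system.file("extdata", "bovine_rhodopsin.fasta", package = "rhodup",
                mustWork = TRUE))
  fa[[1]]
}

#' Map a rhodopsin protein sequence to bovine numbering
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) against the bovine
#' reference; gapped columns are excluded from the map. Sequences whose
#' alignment covers less than half of the key-site region (bovine positions
#' 83-317) are flagged unmappable.
#'
#' @param seq Amino-acid sequence (character or `AAString`), >= 50 residues.
#' @return Integer vector `map` of length 348: `map[b]` is the query index
#'   aligned to bovine position `b` (NA at gaps). The query length is
#'   attached as an attribute.
#' @export
map_to_bovine <- function(seq) {
  seq <- as.character(seq)
  if (nchar(seq) < 50) stop("sequence too short to map (< 50 residues)")
  ref <- bovine_rhodopsin()
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq), subject = ref,
    type = "global", substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, length(ref))
  qpos <- 0L
  bpos <- 0L
  for (i in seq_along(qa)) {
    if (qa[i] != "-") qpos <- qpos + 1L
    if (sa[i] != "-") {
      bpos <- bpos + 1L
      if (qa[i] != "-") map[bpos] <- qpos
    }
  }
  region <- 83:317
  if (mean(!is.na(map[region])) < 0.5) {
    stop("unmappable: alignment covers < 50% of the key-site region")
  }
  attr(map, "query_length") <- nchar(seq)
  map
}

#' Compare two paralogous rhodopsins at the key sites
#'
#' Maps both sequences to bovine numbering and reports the residue pair at
#' every key (and extra) site, which sites differ, and how many. Sites
#' unmapped in either sequence are reported as indeterminate and excluded
#' from the difference count.
#'
#' @param seq_a,seq_b Amino-acid sequences (character or `AAString`).
#' @param table Site table, see [key_site_table()].
#' @return Data frame `site`, `class` ("key"/"extra"), `residue_a`,
#'   `residue_b`, `differs` (NA when indeterminate), with the number of
#'   differing sites in `attr(, "n_differing")`.
#' @export
compare_paralog_key_sites <- function(seq_a, seq_b, table = key_site_table()) {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  map_a <- map_to_bovine(seq_a)
  map_b <- map_to_bovine(seq_b)
  sites <- c(table$key_sites, table$extra_sites)
  classes <- c(rep("key", length(table$key_sites)),
               rep("extra", length(table$extra_sites)))
  res_a <- res_b <- character(length(sites))
  differs <- rep(NA, length(sites))
  chars_a <- strsplit(seq_a, "")[[1]]
  chars_b <- strsplit(seq_b, "")[[1]]
  for (i in seq_along(sites)) {
    qa <- map_a[sites[i]]
    qb <- map_b[sites[i]]
    res_a[i] <- if (is.na(qa)) NA_character_ else chars_a[qa]
    res_b[i] <- if (is.na(qb)) NA_character_ else chars_b[qb]
    if (!is.na(res_a[i]) && !is.na(res_b[i]) &&
        !res_a[i] %in% c("X", "*") && !res_b[i] %in% c("X", "*")) {
      differs[i] <- res_a[i] != res_b[i]
    }
  }
  out <- data.frame(site = sites, class = classes, residue_a = res_a,
                    residue_b = res_b, differs = differs)
  attr(out, "n_differing") <- sum(differs, na.rm = TRUE)
  out
}

#' Translate an in-frame coding alignment
#'
#' @param aln An `rh1_alignment` (gaps removed per sequence before
#'   translation; fuzzy codons become X).
#' @param frame 0-based frame offset.
#' @return Named character vector of amino-acid sequences.
#' @export
translate_cds <- function(aln, frame = attr(aln, "frame_offset") %||% 0L) {
  out <- character(nrow(aln))
  names(out) <- rownames(aln)
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, aln[i, ] != "-"], collapse = "")
    s <- substr(s, frame + 1L, nchar(s))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    aa <- Biostrings::translate(Biostrings::DNAString(s),
                                if.fuzzy.codon = "solve")
    out[i] <- as.character(aa)
  }
  out
}
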