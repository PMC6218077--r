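test_that("FASTA read/write round-trips alignment content", {
  aln <- new_alignment(c(tax1 = "ATGCRYATGCATGCATGCAT",
                         tax2 = "ATGCATKCAT--GCNTGCAT"))
  for (wrap in c(7L, Inf)) {
    path <- tempfile(fileext = ".fasta")
    write_fasta_alignment(aln, path, wrap = wrap)
    back <- read_fasta_alignment(path)
    expect_identical(unclass(back), unclass(aln))
  }
})

test_that("codon positions follow the frame offset", {
  aln <- new_alignment(c(x = "AAAAAAAA", y = "CCCCCCCC"), frame_offset = 2L)
  expect_identical(codon_positions(aln),
                   c(NA, NA, 1L, 2L, 3L, 1L, 2L, 3L))
})

test_that("composition test is exact on hand-computable tables", {
  # perfectly homogeneous counts
  seqs <- c(a = paste(rep(c("A", "C", "G", "T"), 25), collapse = ""),
            b = paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  aln <- new_alignment(vapply(seqs, function(s) {
    paste(rep(strsplit(s, "")[[1]], each = 3), collapse = "")
  }, ""))
  ct <- composition_homogeneity_test(aln, 1)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)

  # 2 taxa, (90A,10T) vs (10A,90T): hand-expanded chi2 = 128, df 3 under the
  # 4-base convention
  s1 <- paste(c(rep("A", 90), rep("T", 10)), collapse = "")
  s2 <- paste(c(rep("A", 10), rep("T", 90)), collapse = "")
  one_pos <- function(s) paste0(vapply(strsplit(s, "")[[1]],
                                       function(ch) paste0(ch, "NN"), ""),
                                collapse = "")
  aln2 <- new_alignment(c(p = one_pos(s1), q = one_pos(s2)))
  ct2 <- composition_homogeneity_test(aln2, 1)
  expect_equal(ct2$statistic, 128)
  expect_equal(ct2$df, 3L)
})

test_that("taxa with no countable bases are dropped with a warning", {
  aln <- new_alignment(c(a = "ATGATG", b = "ATTATG", c = "NNNNNN"))
  expect_warning(ct <- composition_homogeneity_test(aln, 1), "dropping")
  expect_equal(nrow(ct$counts), 2L)
  expect_equal(ct$df, 3L)
})

test_that("composition counts sum to column-wise base totals", {
  d <- random_quartet_data(31, sites = 90)
  counts <- Reduce(`+`, lapply(1:3, function(p) {
    composition_base_counts(d$aln, p)
  }))
  v <- as.vector(unclass(d$aln))
  expect_equal(unname(colSums(counts)),
               vapply(c("A", "C", "G", "T"),
                      function(b) sum(v == b), numeric(1)),
               ignore_attr = TRUE)
})

test_that("RY recoding applies the purine/pyrimidine projection at position 3", {
  aln <- new_alignment(c(x = "ATG", y = "ATA"))
  ry <- ry_recode(aln)
  expect_equal(paste(ry["x", ], collapse = ""), "ATR")
  expect_equal(paste(ry["y", ], collapse = ""), "ATR")

  # ambiguity codes: within-purine/pyrimidine codes project, spanning -> N
  aln2 <- new_alignment(c(x = "AARAAYAAKAASAAWAA-AAN", y = "AACAAGAATAABAADAAHAAV"))
  ry2 <- ry_recode(aln2)
  expect_equal(paste(ry2["x", ], collapse = ""), "AARAAYAANAANAANAA-AAN")
  expect_equal(paste(ry2["y", ], collapse = ""), "AAYAARAAYAANAANAANAAN")

  # idempotent, and positions 1-2 untouched
  expect_identical(unclass(ry_recode(ry2)), unclass(ry2))
  expect_identical(unclass(ry2)[, -seq(3, 21, by = 3)],
                   unclass(aln2)[, -seq(3, 21, by = 3)])
})
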