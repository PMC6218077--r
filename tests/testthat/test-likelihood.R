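test_that("pruning matches exhaustive ancestral-state enumeration", {
  mod <- test_model()
  tops <- c("((A:0.1,B:0.25):0.07,(C:0.3,D:0.12):0.2);",
            "((A:0.1,C:0.25):0.07,(B:0.3,D:0.12):0.2);",
            "((A:0.1,D:0.25):0.07,(B:0.3,C:0.12):0.2);")
  set.seed(11)
  for (tp in tops) {
    tr <- ape::read.tree(text = tp)
    for (rep in 1:4) {
      st <- setNames(sample.int(4, 4, replace = TRUE), c("A", "B", "C", "D"))
      aln <- new_alignment(setNames(c("A", "C", "G", "T")[st], names(st)))
      got <- site_log_likelihoods(tr, aln, mod)$site_lnl[1]
      expect_equal(got, brute_site_loglik(tr, st, mod), tolerance = 1e-10)
    }
  }
})

test_that("fully ambiguous columns have likelihood one", {
  mod <- test_model()
  aln <- new_alignment(c(A = "N-", B = "NN", C = "N?", D = "NN"))
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,(C:0.1,D:0.3):0.1);")
  expect_equal(site_log_likelihoods(tr, aln, mod)$site_lnl,
               c(0, 0), tolerance = 1e-12)
})

test_that("log-likelihood is invariant to re-rooting (pulley principle)", {
  mod <- test_model()
  truth <- simulate_gene_tree(rh1_species_tree(), "B6", seed = 3)
  aln <- simulate_alignment(truth, simulation_model(site_count = 200),
                            seed = 3)
  utr <- ape::unroot(truth$gene_tree)
  base <- tree_log_likelihood(utr, aln, mod)
  for (tip in utr$tip.label) {
    rt <- ape::root(utr, outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rt, aln, mod), base, tolerance = 1e-8)
  }
})

test_that("removing ambiguity can only lower the site likelihood", {
  mod <- test_model()
  d <- random_quartet_data(17, sites = 40)
  amb <- unclass(d$aln)
  amb[1, seq(1, 40, by = 4)] <- "N"
  # R is a superset only of purines; apply it where the base allows
  purine <- which(amb[2, ] %in% c("A", "G"))
  amb[2, purine] <- "R"
  aln_amb <- new_alignment(amb)
  l_amb <- site_log_likelihoods(d$tree, aln_amb, mod)$site_lnl
  l_res <- site_log_likelihoods(d$tree, d$aln, mod)$site_lnl
  expect_true(all(l_res <= l_amb + 1e-10))
})

test_that("pattern compression does not change the total log-likelihood", {
  mod <- test_model()
  d <- random_quartet_data(23, sites = 60)
  dup <- new_alignment(unclass(d$aln)[, c(1:60, 1:30, 5:20)])
  patt <- compress_patterns(dup)
  expect_lt(ncol(patt$mat), ncol(dup))
  per_site <- site_log_likelihoods(d$tree, dup, mod)
  expect_equal(per_site$total, sum(per_site$site_lnl), tolerance = 1e-9)
  expect_equal(per_site$total,
               sum(site_log_likelihoods(d$tree, d$aln, mod)$site_lnl[
                 c(1:60, 1:30, 5:20)]),
               tolerance = 1e-9)
})

test_that("total log-likelihood agrees with an independent implementation", {
  mod <- test_model()
  truth <- simulate_gene_tree(rh1_species_tree(), "B5", seed = 8)
  aln <- simulate_alignment(truth, simulation_model(site_count = 400),
                            seed = 8)
  utr <- ape::unroot(truth$gene_tree)
  ours <- tree_log_likelihood(utr, aln, mod)
  pd <- phangorn::phyDat(tolower(unclass(aln)), type = "DNA")
  ref <- phangorn::pml(utr, pd, bf = mod$base_freqs, Q = mod$rates,
                       shape = mod$gamma_shape, k = mod$n_categories)$logLik
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("site log-likelihood matrix writer/reader round-trips", {
  mod <- test_model()
  d <- random_quartet_data(29, sites = 30)
  trees <- list(t1 = d$tree, t2 = nni_neighbors(d$tree)[[1]])
  mat <- site_loglik_matrix(trees, d$aln, mod)
  expect_equal(colnames(mat), c("t1", "t2"))
  expect_equal(unname(colSums(mat)),
               vapply(trees, tree_log_likelihood, numeric(1),
                      aln = d$aln, model = mod),
               ignore_attr = TRUE, tolerance = 1e-8)
  path <- tempfile(fileext = ".tsv")
  write_sitelik_matrix(mat, path)
  expect_equal(read_sitelik_matrix(path), mat, tolerance = 1e-10)
})

test_that("missing sequences and empty alignments are rejected", {
  mod <- test_model()
  d <- random_quartet_data(5, sites = 10)
  tr5 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  expect_error(site_log_likelihoods(tr5, d$aln, mod), "without sequence")
})
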