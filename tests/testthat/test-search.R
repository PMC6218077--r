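test_that("constraint compatibility follows bipartition containment", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_true(is_compatible(tr, star))
  expect_false(is_compatible(tr, ape::read.tree(text = "((A,C),B,D);")))
  expect_true(is_compatible(tr, tr))
  # constraint over a taxon subset of a larger tree
  big <- ape::read.tree(text = "(((A:1,B:1):1,E:1):1,((C:1,F:1):1,D:1):1);")
  expect_true(is_compatible(big, ape::read.tree(text = "((A,B),C,D);")))
  expect_false(is_compatible(big, ape::read.tree(text = "((A,C),B,D);")))
})

test_that("NNI neighbours of a quartet are the two alternative topologies", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  nb <- nni_neighbors(tr)
  expect_length(nb, 2L)
  keys <- vapply(nb, function(t) paste(sort(split_keys(t)), collapse = ";"),
                 "")
  want <- vapply(list(ape::read.tree(text = "((A,C),(B,D));"),
                      ape::read.tree(text = "((A,D),(B,C));")),
                 function(t) paste(sort(split_keys(t)), collapse = ";"), "")
  expect_setequal(keys, want)
})

test_that("four-taxon search equals exhaustive topology scoring", {
  mod <- test_model()
  d <- random_quartet_data(55, sites = 400)
  fit <- ml_search(d$aln, mod, seed = 3)
  best <- -Inf
  best_top <- NULL
  for (tp in c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")) {
    tt <- ape::read.tree(text = tp)
    tt$edge.length <- rep(0.1, nrow(tt$edge))
    f <- optimize_parameters(tt, d$aln, mod, what = "branch_lengths")
    if (f$lnL > best) {
      best <- f$lnL
      best_top <- ape::read.tree(text = tp)
    }
  }
  expect_equal(fit$lnL, best, tolerance = 1e-4)
  expect_true(is_compatible(fit$tree, best_top))
})

test_that("the search recovers the generating topology and respects constraints", {
  mod <- test_model()
  recovered <- 0L
  for (s in 1:2) {
    set.seed(s)
    tr <- ape::unroot(ape::rtree(8, br = function(n) runif(n, 0.05, 0.3)))
    aln <- simulate_alignment(tr, simulation_model(site_count = 800),
                              seed = s)
    fit <- ml_search(aln, mod, seed = s, n_starts = 2)
    recovered <- recovered + (ape::dist.topo(tr, fit$tree) == 0)
    # with the true topology as constraint, the same tree comes back
    fitc <- ml_search(aln, mod, constraint = tr, seed = s)
    expect_true(is_compatible(fitc$tree, tr))
    expect_equal(ape::dist.topo(fitc$tree, tr), 0, ignore_attr = TRUE)
  }
  expect_gte(recovered, 1L)
})

test_that("bootstrap support is high for a strongly supported quartet split", {
  mod <- test_model()
  tr <- ape::read.tree(text = "((A:0.1,B:0.12):0.15,(C:0.1,D:0.14):0.1);")
  aln <- simulate_alignment(tr, simulation_model(site_count = 1500), seed = 6)
  bt <- bootstrap_support(aln, mod, B = 8, seed = 6, tree = tr)
  expect_true(all(bt$node.label >= 90, na.rm = TRUE))
})

test_that("identical sequences give flagged, undefined support", {
  aln <- new_alignment(matrix("A", nrow = 4, ncol = 30,
                              dimnames = list(c("A", "B", "C", "D"), NULL)))
  mod <- substitution_model()
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  expect_warning(bt <- bootstrap_support(aln, mod, B = 3, seed = 1,
                                         tree = tr), "identical")
  expect_true(all(is.na(bt$node.label)))
})

test_that("support display classes follow the 60/79 rendering convention", {
  expect_equal(support_display_class(c(100, 80, 79, 60, 59.9, NA)),
               c("black", "black", "gray", "gray", "hidden", "hidden"))
})
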