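test_that("uniform characters need no changes", {
  tr <- ape::rtree(6)
  st <- setNames(rep("1", 6), tr$tip.label)
  acr <- fitch_acr(tr, st)
  expect_equal(acr$min_changes, 0L)
  expect_true(all(vapply(acr$node_sets, identical, logical(1), "1")))
})

test_that("Fitch minimum equals the exhaustive minimum on random small trees", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    uni <- as.character(0:sample(1:2, 1))
    st <- setNames(sample(c(uni, "?"), n, replace = TRUE), tr$tip.label)
    if (all(st == "?")) st[1] <- uni[1]
    acr <- fitch_acr(tr, st)
    expect_equal(acr$min_changes,
                 brute_fitch_changes(tr, st, acr$universe),
                 info = paste("case", i))
  }
})

test_that("min changes are invariant to root placement", {
  set.seed(9)
  tr <- ape::rtree(8)
  st <- setNames(sample(c("0", "1", "2", "?"), 8, replace = TRUE),
                 tr$tip.label)
  st[1:2] <- c("0", "2")
  base <- fitch_acr(tr, st)$min_changes
  utr <- ape::unroot(tr)
  for (tip in utr$tip.label[1:5]) {
    rt <- ape::root(utr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_acr(rt, st)$min_changes, base)
  }
})

test_that("adding an all-missing taxon changes nothing", {
  set.seed(15)
  tr <- ape::rtree(6)
  st <- setNames(sample(c("0", "1"), 6, replace = TRUE), tr$tip.label)
  st[1:2] <- c("0", "1")
  base <- fitch_acr(tr, st)$min_changes
  tr2 <- ape::read.tree(text = sub("\\(", "(ghost:1,(",
                                   sub(";", ");", ape::write.tree(tr))))
  st2 <- c(st, ghost = "?")
  expect_equal(fitch_acr(tr2, st2)$min_changes, base)
})

test_that("gain counting matches construction on separated two-state tips", {
  tr <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  st <- setNames(c("2", "1", "1", "1", "1", "1", "2", "1"),
                 letters[1:8])
  expect_equal(count_gains(tr, st, "1", "2"), 2L)
  # within {a,b} the parsimonious gain on the pendant branch of a is counted
  expect_equal(count_gains(tr, st, "1", "2", clade = c("a", "b")), 1L)
  expect_equal(count_gains(tr, st, "1", "2", clade = "a"), 0L)
  # the clade holding only 1-state tips sees no gain
  expect_equal(count_gains(tr, st, "1", "2", clade = c("c", "d")), 0L)
})

test_that("the opsin copy-number matrix implies three independent gains in teleosts", {
  chars <- opsin_character_matrix()
  tree <- jawed_vertebrate_tree()
  cn <- setNames(chars$intronless_rh1_copies, rownames(chars))
  gains <- count_gains(tree, cn, "1", "2", clade = teleost_taxa())
  expect_equal(gains, 3L)
  # single whole-tree events for the other two characters
  expect_equal(fitch_acr(tree, setNames(chars$exo_rh1,
                                        rownames(chars)))$min_changes, 1L)
  expect_equal(fitch_acr(tree, setNames(chars$rh1_intron,
                                        rownames(chars)))$min_changes, 1L)
})

test_that("multifurcations are resolved with a message", {
  tr <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:1);")
  st <- setNames(c("0", "1", "0", "1"), c("a", "b", "c", "d"))
  expect_message(acr <- fitch_acr(tr, st), "resolved")
  expect_equal(acr$min_changes, brute_fitch_changes(acr$tree, st, c("0", "1")))
})
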