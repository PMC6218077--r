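test_that("congruent gene trees reconcile with no events", {
  sp <- rh1_species_tree()
  gt <- sp
  gt$tip.label <- paste0(gt$tip.label, "__rh1")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$D, 0L)
  expect_equal(rec$loss_count, 0L)
})

test_that("a duplicated two-species family reconciles to one duplication", {
  sp <- ape::read.tree(text = "(A:1,B:1);")
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  map <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  rec <- lca_reconcile(gt, sp, leaf_map = map)
  expect_equal(rec$D, 1L)
  expect_equal(rec$loss_count, 0L)
})

test_that("LCA reconciliation attains the exhaustive minimum of D and L", {
  set.seed(61)
  sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  for (rep in 1:8) {
    nleaf <- sample(4:6, 1)
    gt <- ape::rtree(nleaf)
    species <- sample(sp$tip.label, nleaf, replace = TRUE)
    while (length(unique(species)) < 2) {
      species <- sample(sp$tip.label, nleaf, replace = TRUE)
    }
    gt$tip.label <- paste0("g", seq_len(nleaf))
    map <- setNames(species, gt$tip.label)
    rec <- lca_reconcile(gt, sp, leaf_map = map)
    oracle <- brute_reconcile(gt, sp, map)
    expect_equal(rec$D, oracle$D, info = paste("rep", rep))
    expect_equal(rec$loss_count, oracle$L, info = paste("rep", rep))
  }
})

test_that("unrooted input is rejected", {
  sp <- rh1_species_tree()
  gt <- ape::unroot(ape::rtree(5))
  gt$tip.label <- paste0(sp$tip.label, "__x")[1:5]
  expect_error(lca_reconcile(gt, sp), "rooted")
})

test_that("hypothesis families reconcile to D = 3, 2, 1 and B6 loses the older paralog twice", {
  sp <- rh1_species_tree()
  groups <- rh1_species_groups()
  specs <- build_hypothesis_topologies()
  expect_setequal(names(specs), scenario_ids())
  expect_equal(sort(unname(vapply(specs, `[[`, integer(1), "expected_D"))),
               sort(c(3L, 3L, rep(2L, 6), rep(1L, 4))))
  for (spec in specs) {
    truth <- simulate_gene_tree(sp, spec$id, seed = 1)
    rec <- lca_reconcile(truth$gene_tree, sp, species_groups = groups)
    expect_equal(rec$D, spec$expected_D, info = spec$id)
    expect_equal(rec$D, sum(truth$events$kind == "duplication"),
                 info = spec$id)
    expect_equal(rec$loss_count, sum(truth$events$kind == "loss"),
                 info = spec$id)
  }
  # B6: older paralog (Elops_dso + Hiodon_rh1_2 clade) lost twice, in the
  # non-Hiodon osteoglossomorphs and on the Clupeocephala stem
  recB6 <- lca_reconcile(simulate_gene_tree(sp, "B6", seed = 1)$gene_tree,
                         sp, species_groups = groups)
  expect_equal(sort(recB6$loss_locations),
               sort(c("Osteoglossomorpha_other", "Clupeocephala")))
  # C-family: the single duplication sits on the teleost stem
  for (id in paste0("C", 1:4)) {
    expect_equal(specs[[id]]$dup_branches, "Teleostei")
    recC <- lca_reconcile(simulate_gene_tree(sp, id, seed = 1)$gene_tree,
                          sp, species_groups = groups)
    teleost_node <- ape::getMRCA(recC$species_tree,
                                 c("Elops", "Hiodon", "Osteo", "Clupeo"))
    expect_equal(unname(recC$node_map[recC$duplication_nodes]), teleost_node)
  }
})

test_that("pruning a gene-tree leaf never increases the duplication count", {
  sp <- rh1_species_tree()
  for (id in c("A1", "B6", "C2")) {
    truth <- simulate_gene_tree(sp, id, seed = 2)
    gt <- truth$gene_tree
    rec <- lca_reconcile(gt, sp)
    for (leaf in gt$tip.label) {
      sub <- ape::drop.tip(gt, leaf)
      if (length(unique(sub("__.*$", "", sub$tip.label))) < 2) next
      rec2 <- lca_reconcile(sub, sp)
      expect_lte(rec2$D, rec$D)
    }
  }
})

test_that("constraint expansion keeps lineages unresolved and covers outgroups", {
  sp <- rh1_species_tree("full")
  g <- rh1_species_groups("full")
  truth <- simulate_gene_tree(sp, "B6", seed = 3, species_groups = g)
  lmap <- data.frame(taxon = truth$leaf_map$leaf, tag = truth$leaf_map$tag)
  cons <- expand_constraint(build_hypothesis_topologies("B6")[[1]], lmap)
  expect_setequal(cons$tip.label, truth$leaf_map$leaf)
  # the realised gene tree satisfies its own scenario's constraint
  expect_true(is_compatible(truth$gene_tree, cons))
  # ...but not the constraint of a different family
  consC1 <- expand_constraint(build_hypothesis_topologies("C1")[[1]], lmap)
  expect_false(is_compatible(truth$gene_tree, consC1))
})

test_that("orthology placement recovers the generating sister lineage", {
  sp <- rh1_species_tree("full")
  g <- rh1_species_groups("full")
  # Albula keeps only its dso-derived copy: its placement with Elops_dso
  # should beat Elops_fwo
  truth <- simulate_gene_tree(
    sp, "B6", seed = 13, species_groups = g,
    loss_spec = list(list(tag = "Elops_fwo", tips = "Albula")))
  aln <- simulate_alignment(truth, simulation_model(site_count = 1000),
                            seed = 13)
  keep <- truth$leaf_map$leaf[truth$leaf_map$species %in%
                                c("Elops", "Anguilla", "Albula",
                                  "Scyliorhinus", "Raja")]
  sub <- new_alignment(unclass(aln)[keep, , drop = FALSE])
  lmap <- data.frame(taxon = keep, tag = sub("^.*?__", "", keep))
  query <- "Albula__Elops_dso"
  lmap$tag[lmap$taxon == query] <- "query"
  res <- orthology_placement(query, c("Elops_dso", "Elops_fwo"),
                             sub, test_model(), lineage_map = lmap,
                             seed = 13)
  expect_equal(res$candidate[res$rank == 1], "Elops_dso")
})
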