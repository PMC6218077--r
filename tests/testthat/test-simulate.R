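test_that("every scenario realises its defined duplication count", {
  sp <- rh1_species_tree()
  for (id in scenario_ids()) {
    truth <- simulate_gene_tree(sp, id, seed = 1)
    expect_equal(sum(truth$events$kind == "duplication"),
                 scenario_dup_count(id), info = id)
    # every leaf maps to exactly one extant species
    expect_true(all(truth$leaf_map$species %in% sp$tip.label), info = id)
    expect_equal(anyDuplicated(truth$leaf_map$leaf), 0L, info = id)
  }
})

test_that("the truth record is reproducible and user losses are bookkept", {
  sp <- rh1_species_tree("full")
  g <- rh1_species_groups("full")
  loss <- list(list(tag = "Elops_fwo", tips = c("Elops")),
               list(tag = "Elops_fwo", tips = c("Albula", "Notacanthus")))
  t1 <- simulate_gene_tree(sp, "B6", loss_spec = loss, seed = 9,
                           species_groups = g)
  t2 <- simulate_gene_tree(sp, "B6", loss_spec = loss, seed = 9,
                           species_groups = g)
  expect_identical(ape::write.tree(t1$gene_tree), ape::write.tree(t2$gene_tree))
  expect_identical(t1$events, t2$events)
  expect_equal(sum(t1$events$kind == "loss"), 4L)  # 2 implied + 2 requested
  expect_false(any(c("Elops__Elops_fwo", "Albula__Elops_fwo",
                     "Notacanthus__Elops_fwo") %in% t1$gene_tree$tip.label))
  expect_true("Megalops__Elops_fwo" %in% t1$gene_tree$tip.label)
  expect_error(
    simulate_gene_tree(sp, "B6", species_groups = g,
                       loss_spec = list(list(tag = "Osteo_rh1",
                                             tips = g$osteoglossomorpha_other))),
    "entirely")
  expect_error(simulate_gene_tree(sp, "nope", species_groups = g), "unknown")
})

test_that("sequence simulation is deterministic and degenerate cases behave", {
  truth <- simulate_gene_tree(rh1_species_tree(), "C1", seed = 2)
  sm <- simulation_model(site_count = 120)
  a1 <- simulate_alignment(truth, sm, seed = 5)
  a2 <- simulate_alignment(truth, sm, seed = 5)
  expect_identical(unclass(a1), unclass(a2))
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta_alignment(a1, f1); write_fasta_alignment(a2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero branch lengths: all sequences equal the root draw
  tr0 <- truth$gene_tree
  tr0$edge.length[] <- 0
  a0 <- simulate_alignment(tr0, sm, seed = 5)
  expect_equal(nrow(unique(unclass(a0))), 1L)
})

test_that("tip composition converges to the stationary frequencies", {
  tr <- ape::read.tree(text = "(A:0.0,B:50.0);")
  sm <- simulation_model(site_count = 10000, gamma_shape = 50)
  aln <- simulate_alignment(tr, sm, seed = 3)
  freq <- table(factor(unclass(aln)["B", ], levels = c("A", "C", "G", "T")))
  freq <- as.numeric(freq) / 10000
  sigma <- sqrt(sm$model$base_freqs * (1 - sm$model$base_freqs) / 10000)
  expect_true(all(abs(freq - sm$model$base_freqs) < 3 * sigma + 1e-3))
})

test_that("a skewed third-position override creates position-3 heterogeneity only", {
  truth <- simulate_gene_tree(rh1_species_tree(), "B6", seed = 1)
  hits3 <- 0L
  hits12 <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    sm <- simulation_model(
      site_count = 996,
      third_position_freq_override = c(0.05, 0.45, 0.45, 0.05),
      override_taxa = c("Clupeo", "Osteo", "Hiodon"))
    a <- simulate_alignment(truth, sm, seed = s)
    p <- vapply(1:3, function(cp) {
      composition_homogeneity_test(a, cp)$p_value
    }, numeric(1))
    hits3 <- hits3 + (p[3] < 0.05)
    hits12 <- hits12 + (p[1] > 0.05 && p[2] > 0.05)
  }
  expect_gte(hits3, round(0.9 * n_rep))
  expect_gte(hits12, round(0.9 * n_rep))
})

test_that("unconstrained search plus reconciliation recovers the true duplication count", {
  sp <- rh1_species_tree()
  mod <- substitution_model(base_freqs = c(0.23, 0.28, 0.23, 0.26),
                            gamma_shape = 0.5)
  hits <- 0L
  cases <- list(c("C1", 1), c("B6", 2), c("A1", 3))
  for (cs in cases) {
    truth <- simulate_gene_tree(sp, cs[[1]], seed = 31)
    aln <- simulate_alignment(truth, simulation_model(site_count = 3000),
                              seed = 31)
    fit <- ml_search(aln, mod, seed = 31)
    rooted <- ape::root(fit$tree, outgroup = "Outgroup__outgroup_rh1",
                        resolve.root = TRUE)
    rec <- lca_reconcile(rooted, sp)
    hits <- hits + (rec$D == as.integer(cs[[2]]))
  }
  expect_gte(hits, 2L)
})

test_that("gene family bundles round-trip through disk", {
  truth <- simulate_gene_tree(rh1_species_tree(), "A2", seed = 4)
  aln <- simulate_alignment(truth, simulation_model(site_count = 60), seed = 4)
  dir <- tempfile()
  write_gene_family(truth, aln, dir)
  expect_setequal(list.files(dir),
                  c("alignment.fasta", "gene_tree.nwk", "species_tree.nwk",
                    "truth.json"))
  back <- read_fasta_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(unclass(back), unclass(aln))
  gt <- ape::read.tree(file.path(dir, "gene_tree.nwk"))
  expect_setequal(gt$tip.label, truth$gene_tree$tip.label)
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth_json$scenario_id, "A2")
})
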