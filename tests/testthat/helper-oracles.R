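# Independent oracles used across tests. These deliberately avoid the code
# paths they check: likelihoods by exhaustive ancestral-state enumeration,
# parsimony by exhaustive internal-state assignment, reconciliation by
# exhaustive valid-mapping search.

# single-site likelihood by summing over all internal-state assignments
brute_site_loglik <- function(tree, tip_states, model) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  internal <- (ntip + 1):nn
  root <- edge[nrow(edge), 1]
  total <- 0
  for (ci in seq_len(model$n_categories)) {
    r <- model$category_rates[ci]
    Ps <- lapply(seq_len(nrow(edge)),
                 function(e) prob_matrix(model, elen[e], r))
    combs <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    s <- 0
    for (row in seq_len(nrow(combs))) {
      a <- integer(nn)
      a[seq_len(ntip)] <- tip_states[po$tip.label]
      a[internal] <- combs[row, ]
      p <- unname(model$base_freqs[a[root]])
      for (e in seq_len(nrow(edge))) {
        p <- p * Ps[[e]][a[edge[e, 1]], a[edge[e, 2]]]
      }
      s <- s + p
    }
    total <- total + s / model$n_categories
  }
  log(total)
}

# exhaustive Fitch oracle: minimum changes over all internal assignments
brute_fitch_changes <- function(tree, states, universe) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  internal <- (ntip + 1):nn
  tipsets <- lapply(po$tip.label, function(tx) {
    s <- states[[tx]]
    if (s %in% c("?", NA)) universe else s
  })
  combs <- as.matrix(expand.grid(rep(list(universe), length(internal))))
  best <- Inf
  for (row in seq_len(nrow(combs))) {
    a <- vector("list", nn)
    a[internal] <- combs[row, ]
    # tips free over their allowed sets: choose per-tip state minimising the
    # single pendant edge, which is optimal independently per tip
    chg <- 0
    for (e in seq_len(nrow(edge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      if (v <= ntip) {
        chg <- chg + min(as.numeric(!tipsets[[v]] %in% a[[u]]))
      } else {
        chg <- chg + as.numeric(a[[v]] != a[[u]])
      }
    }
    best <- min(best, chg)
  }
  best
}

# exhaustive reconciliation oracle: minimum D and L over all valid maps
brute_reconcile <- function(gene_tree, species_tree, leaf_map) {
  sp_used <- unique(unname(leaf_map))
  sp <- ape::keep.tip(species_tree, sp_used)
  nsp <- length(sp$tip.label)
  spn <- nsp + sp$Nnode
  parent <- rep(NA_integer_, spn)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  anc <- lapply(seq_len(spn), function(n) {
    path <- n
    while (!is.na(parent[path[length(path)]])) {
      path <- c(path, parent[path[length(path)]])
    }
    path
  })
  depth <- lengths(anc) - 1L
  is_anc <- function(a, b) a %in% anc[[b]]  # a ancestor-or-equal of b

  gt <- ape::reorder.phylo(gene_tree, "postorder")
  ngtip <- length(gt$tip.label)
  ngn <- ngtip + gt$Nnode
  internal <- (ngtip + 1):ngn
  fixed <- integer(ngn)
  for (i in seq_len(ngtip)) {
    fixed[i] <- match(leaf_map[[gt$tip.label[i]]], sp$tip.label)
  }
  combs <- as.matrix(expand.grid(rep(list(seq_len(spn)), length(internal))))
  bestD <- Inf
  bestL <- Inf
  for (row in seq_len(nrow(combs))) {
    M <- fixed
    M[internal] <- combs[row, ]
    ok <- TRUE
    D <- 0
    L <- 0
    for (e in seq_len(nrow(gt$edge))) {
      u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
      if (!is_anc(M[u], M[v])) { ok <- FALSE; break }
    }
    if (!ok) next
    # a node is a speciation only if its children descend through distinct
    # children of its own map; anything else is a duplication
    first_step <- function(m, x) {
      if (m == x) return(NA_integer_)
      path <- anc[[x]]
      path[match(m, path) - 1L]
    }
    dup <- logical(ngn)
    gchildren <- vector("list", ngn)
    for (e in seq_len(nrow(gt$edge))) {
      gchildren[[gt$edge[e, 1]]] <- c(gchildren[[gt$edge[e, 1]]],
                                      gt$edge[e, 2])
    }
    for (u in internal) {
      steps <- vapply(gchildren[[u]], function(v) first_step(M[u], M[v]),
                      integer(1))
      dup[u] <- anyNA(steps) || anyDuplicated(steps) > 0
    }
    D <- sum(dup[internal])
    for (e in seq_len(nrow(gt$edge))) {
      u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
      k <- depth[M[v]] - depth[M[u]]
      L <- L + if (dup[u]) k else k - 1
    }
    if (D < bestD) bestD <- D
    if (L < bestL) bestL <- L
  }
  list(D = bestD, L = bestL)
}

# small random in-frame alignment for engine tests
random_quartet_data <- function(seed, sites = 50, gamma_shape = 0.6) {
  set.seed(seed)
  tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.4))
  tr$tip.label <- c("A", "B", "C", "D")
  aln <- simulate_alignment(
    ape::unroot(tr),
    simulation_model(site_count = sites, gamma_shape = gamma_shape),
    seed = seed)
  list(tree = ape::unroot(tr), aln = aln)
}

test_model <- function() {
  substitution_model(rates = c(1.3, 3, 0.8, 1.1, 4, 1),
                     base_freqs = c(0.3, 0.2, 0.25, 0.25),
                     gamma_shape = 0.7)
}
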