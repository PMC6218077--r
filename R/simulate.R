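#' Simulate a gene family under a duplication/loss scenario
#'
#' Builds a gene tree realizing the chosen scenario on a species tree:
#' duplicated copies are grafted at the midpoint of the duplication branch,
#' branch lengths are inherited from the species tree, copy absences implied
#' by the scenario (e.g. the older paralog missing from non-Hiodon
#' osteoglossomorphs and clupeocephalans under B6) are built in, and
#' additional user-specified losses prune species from a copy. Gene leaves
#' are named `<species>__<lineage tag>`.
#'
#' @param species_tree Rooted binary `phylo` with branch lengths, containing
#'   at least one outgroup (non-teleost) tip.
#' @param scenario_id One of [scenario_ids()].
#' @param loss_spec Optional list of losses, each `list(tag =, tips =)`:
#'   prunes the given species (a clade of the species tree) from that gene
#'   lineage, recorded as one loss event. Requests for species the scenario
#'   already excludes from the lineage are ignored.
#' @param seed Integer seed, recorded in the truth object.
#' @param species_groups Named list mapping the species-tree tips to groups
#'   (`outgroup`, `elopomorpha`, `hiodon`, `osteoglossomorpha_other`,
#'   `clupeocephala`); defaults to [rh1_species_groups()] when the tree
#'   matches a packaged tree.
#' @param dup_rate_multiplier Rate multiplier applied to branches descending
#'   from duplication nodes (default 1: paralogs keep the species-tree rate).
#' @return Object of class `gene_family_truth`: `scenario_id`, `gene_tree`,
#'   `events` (data.frame of duplications/losses with species-tree branch
#'   labels), `leaf_map`, `seed`, plus the inputs.
#' @export
simulate_gene_tree <- function(species_tree, scenario_id, loss_spec = NULL,
                               seed = 1L, species_groups = NULL,
                               dup_rate_multiplier = 1) {
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree)) {
    stop("species tree must be rooted and binary")
  }
  if (is.null(species_groups)) {
    for (w in c("compact", "full")) {
      g <- rh1_species_groups(w)
      if (setequal(unlist(g), species_tree$tip.label)) {
        species_groups <- g
        break
      }
    }
    if (is.null(species_groups)) {
      stop("species_groups must be given for a non-packaged species tree")
    }
  }
  groups <- species_groups
  if (!setequal(unlist(groups), species_tree$tip.label)) {
    stop("species_groups must partition the species-tree tips")
  }
  if (length(groups$outgroup) == 0) stop("species tree needs outgroup tips")
  dup_count <- scenario_dup_count(scenario_id)

  ntip <- length(species_tree$tip.label)
  depths <- ape::node.depth.edgelength(species_tree)
  parent_of <- function(node) {
    e <- species_tree$edge[species_tree$edge[, 2] == node, 1]
    if (length(e) == 0) NA_integer_ else e
  }
  mrca_of <- function(tips) {
    idx <- match(tips, species_tree$tip.label)
    if (anyNA(idx)) stop("unknown species: ",
                         paste(tips[is.na(idx)], collapse = ", "))
    if (length(idx) == 1L) idx else ape::getMRCA(species_tree, idx)
  }

  # lineage content after scenario-implied absences and user losses
  tag_sets <- tag_species_sets(groups)
  events <- data.frame(kind = character(0), branch = character(0),
                       stringsAsFactors = FALSE)
  for (br in .scenario_dup_branches[[scenario_id]]) {
    events <- rbind(events, data.frame(kind = "duplication", branch = br))
  }
  for (br in .scenario_implied_losses[[scenario_id]]) {
    events <- rbind(events, data.frame(kind = "loss", branch = br))
  }
  for (ls in loss_spec %||% list()) {
    if (is.null(ls$tag) || is.null(ls$tips)) {
      stop("each loss_spec entry needs $tag and $tips")
    }
    if (!ls$tag %in% lineage_tags()) stop("unknown lineage tag: ", ls$tag)
    hit <- intersect(ls$tips, tag_sets[[ls$tag]])
    if (length(hit) == 0) next  # scenario already excludes these species
    remaining <- setdiff(tag_sets[[ls$tag]], hit)
    if (length(remaining) == 0) {
      stop("loss would remove lineage ", ls$tag, " entirely; the scenario's ",
           dup_count, " duplication(s) would no longer be observable")
    }
    tag_sets[[ls$tag]] <- remaining
    events <- rbind(events, data.frame(kind = "loss",
                                       branch = clade_name(hit, groups)))
  }

  blueprint <- lineage_topology(scenario_id)
  bp_ntip <- length(blueprint$tip.label)
  bp_children <- function(node) blueprint$edge[blueprint$edge[, 1] == node, 2]

  # species location (node + height above root) of each blueprint node
  bp_species <- function(node) {
    if (node <= bp_ntip) return(tag_sets[[blueprint$tip.label[node]]])
    unique(unlist(lapply(bp_children(node), bp_species)))
  }
  bp_lca <- vapply((bp_ntip + 1):(bp_ntip + blueprint$Nnode),
                   function(n) mrca_of(bp_species(n)), integer(1))
  names(bp_lca) <- as.character((bp_ntip + 1):(bp_ntip + blueprint$Nnode))
  node_lca <- function(n) {
    if (n <= bp_ntip) mrca_of(tag_sets[[blueprint$tip.label[n]]])
    else bp_lca[[as.character(n)]]
  }

  # rooted subtree (newick body + its root height) for one lineage tag
  tag_subtree <- function(tag) {
    sp <- tag_sets[[tag]]
    labels <- paste0(sp, "__", tag)
    if (length(sp) == 1L) {
      tipidx <- match(sp, species_tree$tip.label)
      return(list(str = labels, depth = depths[tipidx]))
    }
    sub <- ape::keep.tip(species_tree, sp)
    sub$tip.label <- paste0(sub$tip.label, "__", tag)
    str <- ape::write.tree(sub)
    str <- sub(";$", "", str)
    list(str = str, depth = depths[mrca_of(sp)])
  }

  build <- function(node) {
    if (node <= bp_ntip) return(tag_subtree(blueprint$tip.label[node]))
    kids <- bp_children(node)
    lca <- node_lca(node)
    is_dup <- any(vapply(kids, function(k) node_lca(k) == lca, logical(1)))
    d <- if (is_dup) {
      p <- parent_of(lca)
      if (is.na(p)) stop("duplication above the species root is not placeable")
      (depths[p] + depths[lca]) / 2
    } else {
      depths[lca]
    }
    parts <- lapply(kids, build)
    lens <- vapply(parts, function(p) max(p$depth - d, 0), numeric(1))
    list(str = paste0("(", paste0(vapply(parts, `[[`, "", "str"),
                                  sprintf(":%.10f", lens), collapse = ","), ")"),
         depth = d)
  }

  fam <- build(bp_ntip + 1L)
  og <- {
    sp <- groups$outgroup
    labels <- paste0(sp, "__outgroup_rh1")
    if (length(sp) == 1L) {
      list(str = labels, depth = depths[match(sp, species_tree$tip.label)])
    } else {
      sub <- ape::keep.tip(species_tree, sp)
      sub$tip.label <- paste0(sub$tip.label, "__outgroup_rh1")
      list(str = sub(";$", "", ape::write.tree(sub)),
           depth = depths[mrca_of(sp)])
    }
  }
  nwk <- paste0("(", og$str, sprintf(":%.10f", og$depth), ",",
                fam$str, sprintf(":%.10f", fam$depth), ");")
  gene_tree <- ape::read.tree(text = nwk)

  if (dup_rate_multiplier != 1) {
    # scale every branch inside a duplicated subtree
    gt_tips_below <- function(node) {
      if (node <= length(gene_tree$tip.label)) {
        return(gene_tree$tip.label[node])
      }
      kids <- gene_tree$edge[gene_tree$edge[, 1] == node, 2]
      unlist(lapply(kids, gt_tips_below))
    }
    dup_leafsets <- list()
    for (n in (bp_ntip + 1):(bp_ntip + blueprint$Nnode)) {
      kids <- bp_children(n)
      if (any(vapply(kids, function(k) node_lca(k) == node_lca(n), logical(1)))) {
        tags <- blueprint$tip.label[intersect(seq_len(bp_ntip),
                                              blueprint_descendants(blueprint, n))]
        dup_leafsets[[length(dup_leafsets) + 1L]] <- unlist(
          lapply(tags, function(tg) paste0(tag_sets[[tg]], "__", tg)))
      }
    }
    for (e in seq_len(nrow(gene_tree$edge))) {
      below <- gt_tips_below(gene_tree$edge[e, 2])
      if (any(vapply(dup_leafsets, function(s) all(below %in% s), logical(1)))) {
        gene_tree$edge.length[e] <- gene_tree$edge.length[e] * dup_rate_multiplier
      }
    }
  }
  gene_tree$edge.length[gene_tree$edge.length < 0] <- 0

  leaves <- gene_tree$tip.label
  leaf_map <- data.frame(
    leaf = leaves,
    species = sub("__.*$", "", leaves),
    tag = sub("^.*?__", "", leaves),
    stringsAsFactors = FALSE)

  structure(
    list(scenario_id = scenario_id, gene_tree = gene_tree, events = events,
         leaf_map = leaf_map, seed = as.integer(seed),
         species_tree = species_tree, species_groups = groups),
    class = "gene_family_truth")
}

# tip indices below a node of a (small) phylo
blueprint_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) blueprint_descendants(tree, k)))
}

#' @export
print.gene_family_truth <- function(x, ...) {
  d <- sum(x$events$kind == "duplication")
  l <- sum(x$events$kind == "loss")
  cat(sprintf("gene_family_truth: scenario %s, %d leaves, D = %d, L = %d (seed %d)\n",
              x$scenario_id, length(x$gene_tree$tip.label), d, l, x$seed))
  invisible(x)
}

#' Sequence simulation model
#'
#' GTR+Gamma model plus the simulation-specific settings: the number of
#' sites and an optional third-codon-position base-frequency override that
#' creates lineage-specific compositional heterogeneity (the override
#' frequencies drive position-3 substitutions on the branches of the taxa in
#' `override_taxa`; by default it applies on every branch, so composition
#' drifts away from the root composition with path length).
#'
#' @param rates,base_freqs,gamma_shape,n_categories As in
#'   [substitution_model()]. Defaults are rod-opsin-like: transition-rich
#'   exchangeabilities and moderate rate heterogeneity.
#' @param site_count Alignment length (996 by default, an in-frame rh1
#'   coding fragment).
#' @param third_position_freq_override Optional length-4 frequency vector for
#'   codon position 3.
#' @param override_taxa Optional set of taxa (species names or gene-leaf
#'   labels) whose branches use the override at position 3.
#' @return Object of class `rh1_sim_model`.
#' @export
simulation_model <- function(rates = c(1.5, 4.0, 1.0, 1.2, 6.0, 1.0),
                             base_freqs = c(0.23, 0.28, 0.23, 0.26),
                             gamma_shape = 0.4, n_categories = 4L,
                             site_count = 996L,
                             third_position_freq_override = NULL,
                             override_taxa = NULL) {
  site_count <- as.integer(site_count)
  if (site_count < 1L) stop("site_count must be positive")
  model <- substitution_model(rates, base_freqs, gamma_shape, n_categories)
  model3 <- NULL
  if (!is.null(third_position_freq_override)) {
    if (site_count %% 3L != 0L) {
      stop("site_count must be divisible by 3 when using a codon-position override")
    }
    model3 <- substitution_model(rates, third_position_freq_override,
                                 gamma_shape, n_categories)
  }
  structure(list(model = model, model3 = model3, site_count = site_count,
                 override_taxa = override_taxa),
            class = "rh1_sim_model")
}

#' Simulate an alignment along a gene tree
#'
#' Sites evolve independently under GTR+Gamma: each site draws a rate
#' category, the root state is drawn from the stationary frequencies, and
#' states propagate down the tree through the exact transition probabilities
#' of each branch. Identical seeds give identical alignments.
#'
#' @param x A `gene_family_truth` or a `phylo` with branch lengths.
#' @param sim_model An [simulation_model()].
#' @param seed Integer seed.
#' @return An `rh1_alignment` (frame offset 0).
#' @export
simulate_alignment <- function(x, sim_model = simulation_model(), seed = 1L) {
  tree <- if (inherits(x, "gene_family_truth")) x$gene_tree else x
  if (!inherits(tree, "phylo")) stop("x must be a gene_family_truth or phylo")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  model <- sim_model$model
  model3 <- sim_model$model3
  nsites <- sim_model$site_count
  k <- model$n_categories
  ntip <- length(tree$tip.label)

  set.seed(derive_seed(seed, 2L))
  cat_idx <- sample.int(k, nsites, replace = TRUE)
  pos3 <- (((seq_len(nsites) - 1L) %% 3L) + 1L) == 3L

  # branches using the position-3 override
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  elen <- tree_po$edge.length
  override_edge <- rep(FALSE, nrow(edge))
  if (!is.null(model3)) {
    if (is.null(sim_model$override_taxa)) {
      override_edge[] <- TRUE
    } else {
      targets <- sim_model$override_taxa
      leaf_hit <- tree$tip.label %in% targets |
        sub("__.*$", "", tree$tip.label) %in% targets
      tips_below <- vector("list", ntip + tree$Nnode)
      for (i in seq_len(ntip)) tips_below[[i]] <- i
      for (e in seq_len(nrow(edge))) {
        par <- edge[e, 1]; chd <- edge[e, 2]
        tips_below[[par]] <- c(tips_below[[par]], tips_below[[chd]])
      }
      for (e in seq_len(nrow(edge))) {
        below <- tips_below[[edge[e, 2]]]
        override_edge[e] <- all(leaf_hit[below])
      }
    }
  }

  root <- edge[nrow(edge), 1L]
  states <- matrix(0L, nrow = ntip + tree$Nnode, ncol = nsites)
  states[root, ] <- sample.int(4L, nsites, replace = TRUE,
                               prob = model$base_freqs)
  # parents before children
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; chd <- edge[e, 2L]
    child_states <- integer(nsites)
    for (ci in seq_len(k)) {
      in_cat <- cat_idx == ci
      P <- prob_matrix(model, elen[e], model$category_rates[ci])
      P3 <- if (override_edge[e]) {
        prob_matrix(model3, elen[e], model3$category_rates[ci])
      } else P
      for (a in 1:4) {
        ii <- which(in_cat & !pos3 & states[par, ] == a)
        if (length(ii) > 0) {
          child_states[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                         prob = P[a, ])
        }
        ii <- which(in_cat & pos3 & states[par, ] == a)
        if (length(ii) > 0) {
          child_states[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                         prob = P3[a, ])
        }
      }
    }
    states[chd, ] <- child_states
  }

  mat <- matrix(.nuc_letters[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip)
  rownames(mat) <- tree$tip.label
  new_alignment(mat, frame_offset = 0L)
}

#' Write a simulated gene family to disk
#'
#' Writes `alignment.fasta`, `gene_tree.nwk`, `species_tree.nwk` and a
#' JSON truth record (`truth.json`) into a directory.
#'
#' @param truth A `gene_family_truth`.
#' @param aln The simulated `rh1_alignment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gene_family <- function(truth, aln, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_alignment(aln, file.path(dir, "alignment.fasta"))
  ape::write.tree(truth$gene_tree, file.path(dir, "gene_tree.nwk"))
  ape::write.tree(truth$species_tree, file.path(dir, "species_tree.nwk"))
  jsonlite::write_json(
    list(scenario_id = truth$scenario_id, seed = truth$seed,
         events = truth$events, leaf_map = truth$leaf_map),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
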