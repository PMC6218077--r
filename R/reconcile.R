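#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the species-tree last common ancestor of its
#' descendant species. A gene node is a duplication iff it maps to the same
#' species node as at least one of its children; losses are counted by the
#' standard path-depth formula along every gene-tree edge (which also counts
#' the whole-clade absences implied by duplications). Species absent from
#' the gene tree entirely are first pruned from the species tree: unsampled
#' is not lost.
#'
#' @param gene_tree Rooted `phylo`. Rooting is semantically load-bearing;
#'   unrooted input is rejected.
#' @param species_tree Rooted `phylo` containing all mapped species.
#' @param leaf_map Named character vector (gene leaf -> species) or a
#'   data.frame with columns `leaf` and `species`. Defaults to stripping a
#'   `"__<tag>"` suffix from the gene leaf labels.
#' @param species_groups Optional group list (see [rh1_species_groups()])
#'   used only to give readable names to loss locations.
#' @return Object of class `rh1_reconciliation`: `node_map` (gene node ->
#'   species node id), `duplication_nodes`, `D`, `loss_count`,
#'   `loss_locations` (labels of the species branches where a copy was
#'   lost), and the pruned species tree used.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map = NULL,
                          species_groups = NULL) {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  leaves <- gene_tree$tip.label
  if (is.null(leaf_map)) {
    leaf_map <- setNames(sub("__.*$", "", leaves), leaves)
  } else if (is.data.frame(leaf_map)) {
    leaf_map <- setNames(leaf_map$species, leaf_map$leaf)
  }
  if (!all(leaves %in% names(leaf_map))) {
    stop("leaf_map must cover every gene-tree leaf")
  }
  sp_used <- unique(unname(leaf_map[leaves]))
  if (!all(sp_used %in% species_tree$tip.label)) {
    stop("species missing from species tree: ",
         paste(setdiff(sp_used, species_tree$tip.label), collapse = ", "))
  }
  if (length(sp_used) < 2) stop("need gene copies from at least 2 species")
  sp <- ape::keep.tip(species_tree, sp_used)

  nsp <- length(sp$tip.label)
  sp_nnode <- nsp + sp$Nnode
  sp_parent <- rep(NA_integer_, sp_nnode)
  sp_parent[sp$edge[, 2]] <- sp$edge[, 1]
  sp_root <- setdiff(sp$edge[, 1], sp$edge[, 2])[1]
  sp_depth <- integer(sp_nnode)
  sp_anc <- vector("list", sp_nnode)
  for (n in seq_len(sp_nnode)) {
    path <- n
    while (!is.na(sp_parent[path[length(path)]])) {
      path <- c(path, sp_parent[path[length(path)]])
    }
    sp_anc[[n]] <- path
    sp_depth[n] <- length(path) - 1L
  }
  sp_lca <- function(x, y) {
    if (x == y) return(x)
    common <- intersect(sp_anc[[x]], sp_anc[[y]])
    common[which.max(sp_depth[common])]
  }
  sp_children <- function(n) sp$edge[sp$edge[, 1] == n, 2]
  sp_tips_below <- function(n) {
    if (n <= nsp) return(sp$tip.label[n])
    unlist(lapply(sp_children(n), sp_tips_below))
  }

  gt <- ape::reorder.phylo(gene_tree, "postorder")
  ngt <- length(gt$tip.label) + gt$Nnode
  M <- integer(ngt)
  for (i in seq_along(gt$tip.label)) {
    M[i] <- match(leaf_map[[gt$tip.label[i]]], sp$tip.label)
  }
  children <- vector("list", ngt)
  for (e in seq_len(nrow(gt$edge))) {
    children[[gt$edge[e, 1]]] <- c(children[[gt$edge[e, 1]]], gt$edge[e, 2])
    if (e == nrow(gt$edge) || gt$edge[e + 1, 1] != gt$edge[e, 1]) {
      par <- gt$edge[e, 1]
      M[par] <- Reduce(sp_lca, M[children[[par]]])
    }
  }
  dup <- vapply(seq_len(ngt), function(v) {
    length(children[[v]]) > 0 && any(M[children[[v]]] == M[v])
  }, logical(1))

  loss_nodes <- integer(0)
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
    # species nodes passed strictly between M(u) and M(v); when u is a
    # duplication M(u) itself is passed too
    path <- sp_anc[[M[v]]]
    between <- path[sp_depth[path] > sp_depth[M[u]] & path != M[v]]
    if (dup[u] && M[v] != M[u]) between <- c(between, M[u])
    for (m in between) {
      on_path <- path[match(m, path) - 1L]
      loss_nodes <- c(loss_nodes, setdiff(sp_children(m), on_path))
    }
  }
  groups <- species_groups
  loss_locations <- vapply(loss_nodes, function(n) {
    tips <- sp_tips_below(n)
    if (!is.null(groups)) clade_name(tips, groups)
    else if (length(tips) == 1) tips
    else paste(sort(tips), collapse = "+")
  }, character(1))

  structure(
    list(node_map = M, duplication_nodes = which(dup),
         D = sum(dup), loss_count = length(loss_nodes),
         loss_locations = unname(loss_locations),
         gene_tree = gt, species_tree = sp),
    class = "rh1_reconciliation")
}

#' @export
print.rh1_reconciliation <- function(x, ...) {
  cat(sprintf("LCA reconciliation: D = %d, L = %d", x$D, x$loss_count))
  if (x$loss_count > 0) {
    cat(" (", paste(x$loss_locations, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Constraint topologies of the duplication/loss hypotheses
#'
#' Builds the twelve hypothesis specifications: each couples a lineage-level
#' constraint topology (how the seven gene lineages group relative to the
#' Elopomorpha / Osteoglossomorpha / Clupeocephala divergences) with the
#' duplication count the scenario implies.
#'
#' @param ids Scenario ids (default all twelve).
#' @return Named list of `hypothesis_spec` objects with fields `id`,
#'   `constraint` (rooted `phylo` over [lineage_tags()]), `expected_D`,
#'   `dup_branches`.
#' @export
build_hypothesis_topologies <- function(ids = scenario_ids()) {
  out <- lapply(ids, function(id) {
    structure(
      list(id = id, constraint = lineage_topology(id),
           expected_D = scenario_dup_count(id),
           dup_branches = .scenario_dup_branches[[id]]),
      class = "hypothesis_spec")
  })
  names(out) <- ids
  out
}

#' Expand a lineage-level constraint to taxon level
#'
#' Each lineage tag is replaced by the (unresolved) set of gene leaves
#' carrying that tag; within-lineage relationships are left free. Outgroup
#' leaves are attached at the base as a free polytomy, so the constraint also
#' enforces monophyly of the teleost gene family.
#'
#' @param spec A `hypothesis_spec` (or a tag-level `phylo`).
#' @param lineage_map Data frame with columns `taxon` and `tag` covering the
#'   analysis taxa; tags not in the constraint (e.g. `outgroup_rh1`) join the
#'   basal polytomy.
#' @return A (generally multifurcating) constraint `phylo`.
#' @export
expand_constraint <- function(spec, lineage_map) {
  tag_tree <- if (inherits(spec, "hypothesis_spec")) spec$constraint else spec
  nwk <- ape::write.tree(tag_tree)
  used <- character(0)
  for (tag in tag_tree$tip.label) {
    taxa <- lineage_map$taxon[lineage_map$tag == tag]
    if (length(taxa) == 0) {
      stop("no taxa carry lineage tag ", tag)
    }
    used <- c(used, taxa)
    rep <- if (length(taxa) == 1) taxa else
      paste0("(", paste(taxa, collapse = ","), ")")
    nwk <- gsub(tag, rep, nwk, fixed = TRUE)
  }
  rest <- setdiff(lineage_map$taxon, used)
  if (length(rest) > 0) {
    nwk <- paste0("(", paste(rest, collapse = ","), ",",
                  sub(";$", "", nwk), ");")
  }
  ape::read.tree(text = nwk)
}

#' Evaluate the duplication/loss hypotheses on an alignment
#'
#' For each hypothesis: builds the taxon-level constraint, runs a constrained
#' ML search, and finally compares all per-hypothesis best trees with the AU
#' test on their site log-likelihood matrix. The report mirrors the usual
#' constrained-topology table: hypothesis, -lnL, rank, au, np.
#'
#' @param aln An `rh1_alignment` whose taxa carry lineage tags.
#' @param model Starting `rh1_model`.
#' @param specs List of `hypothesis_spec` (default all twelve).
#' @param lineage_map Data frame `taxon`/`tag`; defaults to parsing
#'   `"<species>__<tag>"` leaf names.
#' @param n_starts,seed,optimize_model,spr Search settings (see
#'   [ml_search()]). By default model parameters are re-optimised for every
#'   constrained tree; `optimize_model = FALSE` shares the starting model.
#' @param au_scales,au_B AU-test settings.
#' @param alpha Rejection level used for the `rejected_au` / `rejected_np`
#'   columns (no further accept/reject policy is built in).
#' @return Object of class `rh1_hypothesis_eval`: `report` (data.frame),
#'   `fits`, `sitelik` (sites x hypotheses matrix), `au`.
#' @export
evaluate_hypotheses <- function(aln, model,
                                specs = build_hypothesis_topologies(),
                                lineage_map = NULL, n_starts = 1L, seed = 1L,
                                optimize_model = TRUE, spr = FALSE,
                                au_scales = seq(0.5, 1.4, by = 0.1),
                                au_B = 1000L, alpha = 0.05) {
  if (is.null(lineage_map)) {
    lineage_map <- data.frame(taxon = rownames(aln),
                              tag = sub("^.*?__", "", rownames(aln)),
                              stringsAsFactors = FALSE)
  }
  fits <- list()
  start_model <- model
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    constraint <- expand_constraint(spec, lineage_map)
    fits[[spec$id]] <- ml_search(
      aln, start_model, constraint = constraint, n_starts = n_starts,
      seed = derive_seed(seed, i), optimize_model = optimize_model,
      spr = spr)
    # warm-start later constrained fits from the first fitted model
    if (i == 1L && optimize_model) start_model <- fits[[1L]]$model
  }
  trees <- lapply(fits, `[[`, "tree")
  models <- lapply(fits, `[[`, "model")
  sl <- site_loglik_matrix(trees, aln, models)
  au <- au_test(sl, scales = au_scales, B = au_B,
                seed = derive_seed(seed, 999L))
  report <- data.frame(
    hypothesis = au$tree,
    expected_D = vapply(specs[au$tree], `[[`, integer(1), "expected_D"),
    neg_lnL = -au$lnL,
    rank = au$rank,
    au = au$au,
    np = au$np,
    rejected_au = au$au < alpha,
    rejected_np = au$np < alpha,
    row.names = NULL)
  structure(list(report = report, fits = fits, sitelik = sl, au = au,
                 alpha = alpha),
            class = "rh1_hypothesis_eval")
}

#' @export
print.rh1_hypothesis_eval <- function(x, ...) {
  df <- x$report[order(x$report$rank), ]
  df$neg_lnL <- sprintf("%.3f", df$neg_lnL)
  df$au <- sprintf("%.3f", df$au)
  df$np <- sprintf("%.3f", df$np)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Constrained orthology placement of a query lineage
#'
#' Forces the query taxa to group with each candidate lineage in turn and
#' ranks the constrained maximum-likelihood scores, the constrained-topology
#' procedure used to decide which paralog lineage a gene of uncertain
#' orthology belongs to.
#'
#' @param query_taxa Gene leaves to place.
#' @param candidate_tags Lineage tags to test as sisters (>= 2).
#' @param aln An `rh1_alignment`.
#' @param model An `rh1_model`.
#' @param lineage_map As in [evaluate_hypotheses()].
#' @param ... Passed to [ml_search()].
#' @param seed Integer seed.
#' @return Data frame `candidate`, `lnL`, `rank` (1 = best placement).
#' @export
orthology_placement <- function(query_taxa, candidate_tags, aln, model,
                                lineage_map = NULL, seed = 1L, ...) {
  if (length(candidate_tags) < 2) stop("need >= 2 candidate lineages")
  if (is.null(lineage_map)) {
    lineage_map <- data.frame(taxon = rownames(aln),
                              tag = sub("^.*?__", "", rownames(aln)),
                              stringsAsFactors = FALSE)
  }
  lnl <- numeric(length(candidate_tags))
  for (i in seq_along(candidate_tags)) {
    cand_taxa <- lineage_map$taxon[lineage_map$tag == candidate_tags[i]]
    if (length(cand_taxa) == 0) stop("no taxa for tag ", candidate_tags[i])
    rest <- setdiff(rownames(aln), c(cand_taxa, query_taxa))
    nwk <- paste0("(", paste(rest, collapse = ","), ",(",
                  paste(c(cand_taxa, query_taxa), collapse = ","), "));")
    constraint <- ape::read.tree(text = nwk)
    fit <- ml_search(aln, model, constraint = constraint,
                     seed = derive_seed(seed, i), ...)
    lnl[i] <- fit$lnL
  }
  data.frame(candidate = candidate_tags, lnL = lnl,
             rank = rank(-lnl, ties.method = "first"))
}
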