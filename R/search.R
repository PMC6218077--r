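# ---- unrooted tree surgery on a light adjacency-graph representation ----

phylo_to_graph <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n)
  wt <- vector("list", n)
  elen <- tree$edge.length %||% rep(0.1, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; l <- elen[e]
    adj[[u]] <- c(adj[[u]], v); wt[[u]] <- c(wt[[u]], l)
    adj[[v]] <- c(adj[[v]], u); wt[[v]] <- c(wt[[v]], l)
  }
  list(adj = adj, wt = wt, tips = tree$tip.label,
       ntip = length(tree$tip.label))
}

graph_to_phylo <- function(g) {
  ntip <- g$ntip
  if (ntip == 2L) {
    return(ape::read.tree(text = paste0("(", g$tips[1], ":0,",
                                        g$tips[2], ":0);")))
  }
  deg <- vapply(g$adj, length, integer(1))
  start <- which(deg >= 3L)[1]
  if (is.na(start)) start <- g$adj[[1]][1]
  # walk an edge, splicing through degree-2 internal nodes
  walk <- function(node, prev) {
    len <- 0
    repeat {
      i <- which(g$adj[[prev]] == node)[1]
      len <- len + g$wt[[prev]][i]
      if (node <= ntip || length(g$adj[[node]]) != 2L) break
      nxt <- setdiff(g$adj[[node]], prev)[1]
      prev <- node; node <- nxt
    }
    list(node = node, prev = prev, len = len)
  }
  visit <- function(node, parent) {
    if (node <= ntip) return(g$tips[node])
    kids <- setdiff(g$adj[[node]], parent)
    parts <- character(0)
    for (k in kids) {
      w <- walk(k, node)
      parts <- c(parts, paste0(visit(w$node, w$prev),
                               sprintf(":%.12g", w$len)))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  kids <- g$adj[[start]]
  parts <- character(0)
  for (k in kids) {
    w <- walk(k, start)
    parts <- c(parts, paste0(visit(w$node, w$prev), sprintf(":%.12g", w$len)))
  }
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

graph_replace <- function(vec, old, new) {
  vec[which(vec == old)[1]] <- new
  vec
}

# ---- bipartitions and constraint compatibility ----

# canonical keys of the non-trivial bipartitions induced on `taxa`
split_keys <- function(tree, taxa = NULL) {
  taxa <- sort(taxa %||% tree$tip.label)
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    below[[u]] <- c(below[[u]], below[[v]])
    side <- intersect(below[[v]], taxa)
    if (length(side) >= 2 && length(side) <= length(taxa) - 2) {
      if (taxa[1] %in% side) side <- setdiff(taxa, side)
      keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
  }
  unique(keys)
}

#' Test whether a tree satisfies a (multifurcating) constraint tree
#'
#' TRUE iff every non-trivial bipartition induced by the constraint,
#' restricted to the taxa shared with the tree, occurs among the tree's
#' bipartitions restricted likewise.
#'
#' @param tree A `phylo`.
#' @param constraint A `phylo`, possibly multifurcating, over a subset of the
#'   tree's taxa.
#' @return Logical.
#' @export
is_compatible <- function(tree, constraint) {
  shared <- intersect(tree$tip.label, constraint$tip.label)
  if (length(shared) < 4) return(TRUE)
  all(split_keys(constraint, shared) %in% split_keys(tree, shared))
}

# ---- starting trees ----

# random constraint-compatible starting topology over `taxa`
random_start_tree <- function(taxa, constraint = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(constraint)) {
    tr <- ape::rtopology(length(taxa), rooted = FALSE,
                         tip.label = sample(taxa))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    return(tr)
  }
  base <- ape::keep.tip(constraint, intersect(constraint$tip.label, taxa))
  base <- ape::multi2di(base, random = TRUE)
  base <- ape::unroot(base)
  base$edge.length <- rep(0.1, nrow(base$edge))
  extras <- setdiff(taxa, base$tip.label)
  g <- phylo_to_graph(base)
  for (tip in extras) {
    # collect current edges (u < v once)
    edges <- NULL
    for (u in seq_along(g$adj)) {
      for (v in g$adj[[u]]) if (u < v) edges <- rbind(edges, c(u, v))
    }
    e <- edges[sample.int(nrow(edges), 1L), ]
    tipid <- length(g$adj) + 1L
    mid <- length(g$adj) + 2L
    g$tips <- c(g$tips, tip)
    # renumber: tips must occupy 1..ntip; easier to rebuild labels: keep tip
    # ids beyond ntip and fix during newick write instead -> rebuild graph with
    # tip ids first is fiddly; write tip as internal-with-label workaround:
    g$adj[[tipid]] <- integer(0); g$wt[[tipid]] <- numeric(0)
    g$adj[[mid]] <- integer(0); g$wt[[mid]] <- numeric(0)
    iu <- which(g$adj[[e[1]]] == e[2])[1]
    l <- g$wt[[e[1]]][iu]
    g$adj[[e[1]]][iu] <- mid
    g$wt[[e[1]]][iu] <- l / 2
    iv <- which(g$adj[[e[2]]] == e[1])[1]
    g$adj[[e[2]]][iv] <- mid
    g$wt[[e[2]]][iv] <- l / 2
    g$adj[[mid]] <- c(e[1], e[2], tipid)
    g$wt[[mid]] <- c(l / 2, l / 2, 0.1)
    g$adj[[tipid]] <- mid
    g$wt[[tipid]] <- 0.1
    # renormalise node ids so tips come first
    g <- renumber_graph(g, tip_ids = c(seq_len(g$ntip), tipid),
                        labels = g$tips)
  }
  graph_to_phylo(g)
}

renumber_graph <- function(g, tip_ids, labels) {
  n <- length(g$adj)
  internal <- setdiff(which(vapply(g$adj, length, integer(1)) > 0 |
                              seq_len(n) %in% tip_ids), tip_ids)
  old <- c(tip_ids, internal)
  newid <- integer(n)
  newid[old] <- seq_along(old)
  adj <- vector("list", length(old))
  wt <- vector("list", length(old))
  for (o in old) {
    adj[[newid[o]]] <- newid[g$adj[[o]]]
    wt[[newid[o]]] <- g$wt[[o]]
  }
  list(adj = adj, wt = wt, tips = labels, ntip = length(tip_ids))
}

# ---- move sets ----

# all NNI rearrangements of an unrooted binary tree (2 per internal edge)
nni_neighbors <- function(tree) {
  g <- phylo_to_graph(tree)
  out <- list()
  for (u in seq_along(g$adj)) {
    for (v in g$adj[[u]]) {
      if (u >= v || u <= g$ntip || v <= g$ntip) next
      b <- setdiff(g$adj[[u]], v)[1]
      for (swap_c in setdiff(g$adj[[v]], u)) {
        g2 <- g
        ib <- which(g2$adj[[u]] == b)[1]
        ic <- which(g2$adj[[v]] == swap_c)[1]
        lb <- g2$wt[[u]][ib]; lc <- g2$wt[[v]][ic]
        g2$adj[[u]][ib] <- swap_c; g2$wt[[u]][ib] <- lc
        g2$adj[[v]][ic] <- b; g2$wt[[v]][ic] <- lb
        g2$adj[[b]] <- graph_replace(g2$adj[[b]], u, v)
        g2$adj[[swap_c]] <- graph_replace(g2$adj[[swap_c]], v, u)
        out[[length(out) + 1L]] <- graph_to_phylo(g2)
      }
    }
  }
  out
}

# SPR rearrangements with a bounded regraft radius
spr_neighbors <- function(tree, radius = 3L) {
  g <- phylo_to_graph(tree)
  deg <- vapply(g$adj, length, integer(1))
  out <- list()
  for (u in seq_along(g$adj)) {
    for (v in g$adj[[u]]) {
      if (deg[u] < 3) next  # prune the v-side subtree from node u
      # BFS over remaining edges from u, excluding the pruned side
      dist <- rep(NA_integer_, length(g$adj)); dist[u] <- 0L
      queue <- u
      while (length(queue) > 0) {
        x <- queue[1]; queue <- queue[-1]
        for (y in g$adj[[x]]) {
          if ((x == u && y == v) || !is.na(dist[y])) next
          dist[y] <- dist[x] + 1L
          if (dist[y] < radius) queue <- c(queue, y)
        }
      }
      for (x in which(!is.na(dist))) {
        for (y in g$adj[[x]]) {
          if (x >= y || is.na(dist[y]) || (x == u | y == u)) next
          if ((x == u && y == v) || (y == u && x == v)) next
          g2 <- spr_apply(g, u, v, x, y)
          if (!is.null(g2)) out[[length(out) + 1L]] <- graph_to_phylo(g2)
        }
      }
    }
  }
  out
}

spr_apply <- function(g, u, v, x, y) {
  # detach subtree rooted at v (across edge u-v), splice u away if degree 2,
  # then subdivide edge x-y with a new node joined to v
  iu <- which(g$adj[[u]] == v)[1]
  stem <- g$wt[[u]][iu]
  g$adj[[u]] <- g$adj[[u]][-iu]; g$wt[[u]] <- g$wt[[u]][-iu]
  iv <- which(g$adj[[v]] == u)[1]
  ix <- which(g$adj[[x]] == y)[1]
  iy <- which(g$adj[[y]] == x)[1]
  if (is.na(ix) || is.na(iy)) return(NULL)
  l <- g$wt[[x]][ix]
  mid <- length(g$adj) + 1L
  g$adj[[x]][ix] <- mid; g$wt[[x]][ix] <- l / 2
  g$adj[[y]][iy] <- mid; g$wt[[y]][iy] <- l / 2
  g$adj[[mid]] <- c(x, y, v); g$wt[[mid]] <- c(l / 2, l / 2, stem)
  g$adj[[v]][iv] <- mid
  g
}

# ---- search and bootstrap ----

#' Maximum-likelihood topology search
#'
#' Hill-climbing search over NNI (optionally SPR) rearrangements with
#' multiple random-addition starts, honouring an optional multifurcating
#' constraint tree: moves that break a constraint bipartition are rejected.
#' Ties between equally likely topologies are broken by lexicographic Newick
#' order so results are reproducible.
#'
#' @param aln An `rh1_alignment`.
#' @param model Starting `rh1_model`.
#' @param constraint Optional constraint `phylo` (see [is_compatible()]).
#' @param n_starts Number of independent starts.
#' @param seed Integer seed.
#' @param optimize_model Re-optimise model parameters along with branch
#'   lengths.
#' @param spr Also propose SPR moves (radius 3).
#' @param max_rounds Maximum hill-climbing rounds per start.
#' @param taxa Taxa to analyse (default: all alignment rows).
#' @return List with `tree` (unrooted, optimised branch lengths), `lnL`,
#'   `model`.
#' @export
ml_search <- function(aln, model, constraint = NULL, n_starts = 1L,
                      seed = 1L, optimize_model = FALSE, spr = FALSE,
                      max_rounds = 20L, taxa = NULL) {
  taxa <- taxa %||% rownames(aln)
  if (length(taxa) < 4) stop("need >= 4 taxa")
  if (!is.null(constraint)) {
    missing <- setdiff(constraint$tip.label, taxa)
    if (length(missing) > 0) {
      stop("constraint taxa absent from alignment: ",
           paste(missing, collapse = ", "))
    }
  }
  what <- if (optimize_model) "both" else "branch_lengths"
  best <- NULL

  for (s in seq_len(n_starts)) {
    tree <- start_tree_for(aln, taxa, constraint, derive_seed(seed, s),
                           first = (s == 1L))
    fit <- optimize_parameters(tree, aln, model, what = what, max_sweeps = 3L)
    patt <- compress_patterns(aln, taxa = taxa)
    quick_lnl <- function(tr) sum(prune_loglik(tr, patt, fit$model) *
                                    patt$weights)
    for (round in seq_len(max_rounds)) {
      nbrs <- nni_neighbors(fit$tree)
      if (spr) nbrs <- c(nbrs, spr_neighbors(fit$tree, radius = 3L))
      if (!is.null(constraint)) {
        nbrs <- Filter(function(tr) is_compatible(tr, constraint), nbrs)
      }
      if (length(nbrs) == 0) break
      # rank all moves on carried-over branch lengths, then re-optimise the
      # promising ones greedily: accept the first that improves
      raw <- vapply(nbrs, quick_lnl, numeric(1))
      top <- order(raw, decreasing = TRUE)[seq_len(min(3L, length(nbrs)))]
      improved <- FALSE
      for (i in top) {
        cand <- optimize_parameters(nbrs[[i]], aln, fit$model,
                                    what = "branch_lengths",
                                    max_sweeps = 1L, branch_tol = 1e-4)
        if (cand$lnL > fit$lnL + 1e-6) {
          fit <- optimize_parameters(cand$tree, aln, fit$model,
                                     what = what, max_sweeps = 2L)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (is.null(best) || fit$lnL > best$lnL + 1e-6 ||
        (abs(fit$lnL - best$lnL) <= 1e-6 &&
         ape::write.tree(fit$tree) < ape::write.tree(best$tree))) {
      best <- fit
    }
  }
  if (!is.null(constraint) && !is_compatible(best$tree, constraint)) {
    stop("search returned a constraint-incompatible tree; this is a bug")
  }
  list(tree = best$tree, lnL = best$lnL, model = best$model)
}

start_tree_for <- function(aln, taxa, constraint, seed, first = FALSE) {
  if (first && is.null(constraint) && length(taxa) > 4) {
    dn <- ape::as.DNAbin(tolower(unclass(aln)[taxa, , drop = FALSE]))
    d <- ape::dist.dna(dn, model = "JC69", pairwise.deletion = TRUE)
    if (all(is.finite(d))) {
      tr <- ape::unroot(ape::njs(d))
      tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
      return(tr)
    }
  }
  random_start_tree(taxa, constraint, seed)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns, re-searches each pseudo-replicate and
#' reports, for every internal edge of the reference tree, the percentage of
#' replicate trees containing that bipartition (stored in `node.label`).
#'
#' @param aln An `rh1_alignment`.
#' @param model An `rh1_model`.
#' @param B Number of pseudo-replicates.
#' @param seed Integer seed.
#' @param tree Reference tree (searched from `aln` if omitted).
#' @param n_starts Starts per replicate search.
#' @param ... Passed to [ml_search()].
#' @return The reference tree with bootstrap percentages as node labels.
#' @export
bootstrap_support <- function(aln, model, B = 100L, seed = 1L, tree = NULL,
                              n_starts = 1L, ...) {
  if (B < 1) stop("B must be >= 1")
  if (nrow(unique(unclass(aln))) == 1L) {
    warning("all sequences identical: bootstrap support undefined")
    tree <- tree %||% ml_search(aln, model, seed = seed, ...)$tree
    tree$node.label <- rep(NA_real_, tree$Nnode)
    return(tree)
  }
  if (is.null(tree)) {
    tree <- ml_search(aln, model, n_starts = n_starts, seed = seed, ...)$tree
  }
  rep_keys <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 1000L + b))
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    rep_aln <- new_alignment(unclass(aln)[, cols, drop = FALSE],
                             frame_offset = 0L)
    rep_tree <- ml_search(rep_aln, model, n_starts = 1L,
                          seed = derive_seed(seed, 2000L + b), ...)$tree
    rep_keys[[b]] <- split_keys(rep_tree)
  }
  # support per internal edge of the reference tree, attached to child nodes
  tree_po <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tree_po$tip.label)
  taxa <- sort(tree_po$tip.label)
  below <- vector("list", ntip + tree_po$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree_po$tip.label[i]
  labels <- rep(NA_real_, tree_po$Nnode)
  for (e in seq_len(nrow(tree_po$edge))) {
    u <- tree_po$edge[e, 1]; v <- tree_po$edge[e, 2]
    below[[u]] <- c(below[[u]], below[[v]])
    if (v > ntip) {
      side <- below[[v]]
      if (length(side) >= 2 && length(side) <= ntip - 2) {
        if (taxa[1] %in% side) side <- setdiff(taxa, side)
        key <- paste(sort(side), collapse = "\r")
        labels[v - ntip] <- 100 *
          mean(vapply(rep_keys, function(k) key %in% k, logical(1)))
      }
    }
  }
  tree_po$node.label <- round(labels, 1)
  tree_po
}

#' Display class of a bootstrap support value
#'
#' Mirrors the figure convention for rendering nodal support: values above
#' 79% are drawn black, values in 60-79% gray, and values below 60% are not
#' shown.
#'
#' @param support Numeric vector of percentages.
#' @return Character vector in `{"black", "gray", "hidden"}`.
#' @export
support_display_class <- function(support) {
  ifelse(is.na(support), "hidden",
         ifelse(support > 79, "black",
                ifelse(support >= 60, "gray", "hidden")))
}
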