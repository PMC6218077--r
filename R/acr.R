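# state vectors are logical masks over the character's state universe

acr_prepare <- function(tree, states) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) {
    message("multifurcations resolved deterministically for the parsimony pass")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  states <- setNames(as.character(states), names(states))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0) {
    stop("no state for taxa: ", paste(missing, collapse = ", "))
  }
  obs <- states[tree$tip.label]
  universe <- sort(unique(obs[!obs %in% c("?", NA)]))
  if (length(universe) == 0) stop("character has no observed states")
  list(tree = tree, obs = obs, universe = universe)
}

#' Fitch parsimony ancestral-state reconstruction
#'
#' Unordered equal-cost parsimony with missing data: '?' tips carry the full
#' state set. The bottom-up pass counts the minimum number of changes (one
#' per union event); the top-down pass yields the set of states each node
#' takes in at least one most-parsimonious reconstruction.
#'
#' @param tree Rooted `phylo` (multifurcations are resolved deterministically
#'   with a message).
#' @param states Named vector of tip states; `"?"` or `NA` marks missing.
#' @return Object of class `rh1_acr`: `node_sets` (list of state vectors per
#'   node, tips first), `min_changes`, `universe`, `tree` (the binary tree
#'   used).
#' @export
fitch_acr <- function(tree, states) {
  prep <- acr_prepare(tree, states)
  tree <- prep$tree
  universe <- prep$universe
  ns <- length(universe)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  prelim <- matrix(FALSE, nrow = nnode, ncol = ns)
  for (i in seq_len(ntip)) {
    s <- prep$obs[i]
    prelim[i, ] <- if (s %in% c("?", NA)) TRUE else universe == s
    if (!any(prelim[i, ])) stop("tip state outside universe: ", s)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  children <- vector("list", nnode)
  for (e in seq_len(nrow(edge))) {
    children[[edge[e, 1]]] <- c(children[[edge[e, 1]]], edge[e, 2])
  }
  changes <- 0L
  union_node <- logical(nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    if (e < nrow(edge) && edge[e + 1, 1] == par) next
    kids <- children[[par]]
    s <- prelim[kids[1], ]
    for (k in kids[-1]) {
      inter <- s & prelim[k, ]
      if (any(inter)) {
        s <- inter
      } else {
        s <- s | prelim[k, ]
        changes <- changes + 1L
        union_node[par] <- TRUE
      }
    }
    prelim[par, ] <- s
  }

  # top-down (Swofford-Maddison) final sets
  final <- prelim
  root <- edge[nrow(edge), 1]
  final[root, ] <- prelim[root, ]
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; v <- edge[e, 2]
    if (v <= ntip) next
    if (all(final[par, ] <= prelim[v, ])) {
      final[v, ] <- final[par, ]
    } else if (union_node[v]) {
      final[v, ] <- prelim[v, ] | final[par, ]
    } else {
      kids_union <- Reduce(`|`, lapply(children[[v]],
                                       function(k) prelim[k, ]))
      final[v, ] <- prelim[v, ] | (final[par, ] & kids_union)
    }
  }

  node_sets <- lapply(seq_len(nnode), function(n) universe[final[n, ]])
  structure(list(node_sets = node_sets, min_changes = changes,
                 universe = universe, tree = tree),
            class = "rh1_acr")
}

#' @export
print.rh1_acr <- function(x, ...) {
  cat(sprintf("Fitch parsimony ACR: %d minimum changes over states {%s}\n",
              x$min_changes, paste(x$universe, collapse = ", ")))
  invisible(x)
}

#' Minimum number of independent state gains within a clade
#'
#' Among all most-parsimonious reconstructions of the character, counts the
#' minimum number of branches inside the clade whose parent resolves to
#' `from_state` and child to `to_state`. Computed by dynamic programming over
#' Pareto-optimal (changes, gains) pairs, so the answer is exact.
#'
#' @param tree Rooted `phylo`.
#' @param states Named tip-state vector ('?' = missing).
#' @param from_state,to_state The transition to count.
#' @param clade Tip labels (or a node number) delimiting the clade; edges
#'   counted are those strictly inside it. Default: the whole tree.
#' @return Integer minimum gain count.
#' @export
count_gains <- function(tree, states, from_state, to_state, clade = NULL) {
  prep <- acr_prepare(tree, states)
  tree <- prep$tree
  universe <- prep$universe
  from_i <- match(as.character(from_state), universe)
  to_i <- match(as.character(to_state), universe)
  if (is.na(from_i) || is.na(to_i)) stop("transition states not in universe")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  # which nodes lie inside the clade
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  in_clade <- rep(FALSE, nnode)
  if (is.null(clade)) {
    in_clade[] <- TRUE
  } else {
    if (is.character(clade)) {
      idx <- match(clade, tree$tip.label)
      if (anyNA(idx)) stop("unknown clade tips")
      croot <- if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
    } else {
      croot <- as.integer(clade)
    }
    mark <- function(n) {
      in_clade[n] <<- TRUE
      for (k in edge[edge[, 1] == n, 2]) mark(k)
    }
    mark(croot)
  }
  if (sum(in_clade) <= 1) return(0L)

  ns <- length(universe)
  INF <- .Machine$integer.max %/% 4L
  # dp[[node]]: ns x 2k matrix-free: list per state of Pareto (changes, gains)
  pareto <- function(p) {
    if (nrow(p) == 0) return(p)
    p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
    keep <- rep(TRUE, nrow(p))
    best_g <- Inf
    for (i in seq_len(nrow(p))) {
      if (p[i, 2] >= best_g) keep[i] <- FALSE else best_g <- p[i, 2]
    }
    p[keep, , drop = FALSE]
  }
  dp <- vector("list", nnode)
  tip_allowed <- function(i) {
    s <- prep$obs[i]
    if (s %in% c("?", NA)) rep(TRUE, ns) else universe == s
  }
  for (i in seq_len(ntip)) {
    dp[[i]] <- lapply(seq_len(ns), function(s) {
      if (tip_allowed(i)[s]) matrix(c(0, 0), 1) else matrix(numeric(0), 0, 2)
    })
  }
  children <- vector("list", nnode)
  for (e in seq_len(nrow(edge))) {
    children[[edge[e, 1]]] <- c(children[[edge[e, 1]]], edge[e, 2])
  }
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    if (e < nrow(edge) && edge[e + 1, 1] == par) next
    kids <- children[[par]]
    dp[[par]] <- lapply(seq_len(ns), function(s) {
      acc <- matrix(c(0, 0), 1)
      for (k in kids) {
        # best pairs for child k given parent state s
        opts <- matrix(numeric(0), 0, 2)
        for (cs in seq_len(ns)) {
          p <- dp[[k]][[cs]]
          if (nrow(p) == 0) next
          add_chg <- as.numeric(cs != s)
          add_gain <- as.numeric(in_clade[par] && in_clade[k] &&
                                   s == from_i && cs == to_i)
          opts <- rbind(opts, cbind(p[, 1] + add_chg, p[, 2] + add_gain))
        }
        opts <- pareto(opts)
        if (nrow(opts) == 0) return(matrix(numeric(0), 0, 2))
        comb <- matrix(numeric(0), 0, 2)
        for (i in seq_len(nrow(acc))) {
          comb <- rbind(comb, cbind(acc[i, 1] + opts[, 1],
                                    acc[i, 2] + opts[, 2]))
        }
        acc <- pareto(comb)
      }
      acc
    })
  }
  root <- edge[nrow(edge), 1]
  all_pairs <- do.call(rbind, dp[[root]])
  if (nrow(all_pairs) == 0) stop("no feasible reconstruction; this is a bug")
  min_changes <- min(all_pairs[, 1])
  as.integer(min(all_pairs[all_pairs[, 1] == min_changes, 2]))
}

#' Packaged jawed-vertebrate backbone tree and opsin character matrix
#'
#' A simplified species phylogeny of jawed vertebrates (Elopomorpha sister
#' to the remaining teleosts; Osteoglossomorpha sister to the Clupeocephala)
#' with a three-character opsin gene matrix: presence of the pineal
#' exo-rhodopsin gene, presence of an intron-containing rh1, and the copy
#' number of intron-less rh1 (0/1/2, '?' where unknown). Lineages whose
#' state is not stated in the literature summarised by the matrix are coded
#' '?'.
#'
#' @return `jawed_vertebrate_tree()`: a rooted `phylo`;
#'   `opsin_character_matrix()`: a data.frame with rownames = taxa and one
#'   column per character; `teleost_taxa()`: the tip labels spanning the
#'   Teleostei clade of that tree.
#' @export
jawed_vertebrate_tree <- function() {
  ape::read.tree(system.file("extdata", "jawed_vertebrate_tree.nwk",
                             package = "rhodup", mustWork = TRUE))
}

#' @rdname jawed_vertebrate_tree
#' @export
opsin_character_matrix <- function() {
  df <- read.delim(system.file("extdata", "opsin_characters.tsv",
                               package = "rhodup", mustWork = TRUE),
                   colClasses = "character")
  rownames(df) <- df$taxon
  df[, setdiff(colnames(df), "taxon"), drop = FALSE]
}

#' @rdname jawed_vertebrate_tree
#' @export
teleost_taxa <- function() {
  c("Elopiformes", "Albuliformes", "Notacanthiformes", "Anguilliformes",
    "Hiodon", "Osteoglossomorpha_other", "Otocephala", "Euteleostei")
}
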