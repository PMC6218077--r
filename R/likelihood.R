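#' Collapse an alignment into unique site patterns
#'
#' @param aln An `rh1_alignment` (or character matrix).
#' @param taxa Optional subset/order of taxa to keep.
#' @return List with `mat` (taxa x patterns character matrix), `weights`
#'   (pattern multiplicities) and `map` (original column -> pattern index).
#' @export
compress_patterns <- function(aln, taxa = NULL) {
  mat <- unclass(aln)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(mat))
    if (length(missing) > 0) {
      stop("taxa without sequence: ", paste(missing, collapse = ", "))
    }
    mat <- mat[taxa, , drop = FALSE]
  }
  if (ncol(mat) == 0L) stop("alignment has zero columns")
  key <- apply(mat, 2, paste, collapse = "")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  pmat <- mat[, uniq, drop = FALSE]
  list(mat = pmat,
       weights = as.vector(table(map)[as.character(seq_len(sum(uniq)))]),
       map = map,
       tip_partials = setNames(lapply(rownames(pmat), function(tx) {
         encode_partials(pmat[tx, ])
       }), rownames(pmat)))
}

# Core pruning pass. Returns per-pattern log-likelihoods.
# tree may be rooted (binary root) or unrooted (basal multifurcation); under a
# reversible model both give the same likelihood.
prune_loglik <- function(tree, patt, model) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have >= 2 tips")
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) stop("tree has no branch lengths")
  if (any(elen < 0)) stop("negative branch length")
  npat <- ncol(patt$mat)
  nnode <- ntip + tree$Nnode
  root <- edge[nrow(edge), 1L]

  tip_part <- if (!is.null(patt$tip_partials)) {
    patt$tip_partials[tree$tip.label]
  } else {
    setNames(lapply(tree$tip.label, function(tx) {
      encode_partials(patt$mat[tx, ])
    }), tree$tip.label)
  }

  k <- model$n_categories
  cat_lnl <- matrix(0, nrow = k, ncol = npat)
  for (ci in seq_len(k)) {
    r <- model$category_rates[ci]
    # transition matrix per edge for this category
    Ps <- lapply(seq_len(nrow(edge)), function(e) prob_matrix(model, elen[e], r))
    part <- vector("list", nnode)
    lsc <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      part[[i]] <- tip_part[[i]]
      lsc[[i]] <- numeric(npat)
    }
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]; chd <- edge[e, 2L]
      contrib <- Ps[[e]] %*% part[[chd]]
      if (is.null(part[[par]])) {
        part[[par]] <- contrib
        lsc[[par]] <- lsc[[chd]]
      } else {
        part[[par]] <- part[[par]] * contrib
        lsc[[par]] <- lsc[[par]] + lsc[[chd]]
      }
      if (e == nrow(edge) || edge[e + 1L, 1L] != par) {
        # parent finished: rescale patterns drifting towards underflow
        pp <- part[[par]]
        mx <- pmax(pp[1L, ], pp[2L, ], pp[3L, ], pp[4L, ])
        sel <- which(mx < 1e-150 & mx > 0)
        if (length(sel) > 0) {
          part[[par]][, sel] <- pp[, sel, drop = FALSE] /
            rep(mx[sel], each = 4L)
          lsc[[par]][sel] <- lsc[[par]][sel] + log(mx[sel])
        }
      }
    }
    lik <- colSums(model$base_freqs * part[[root]])
    cat_lnl[ci, ] <- log(lik) + lsc[[root]]
  }
  # average likelihood over equal-weight rate categories, in log space
  m <- do.call(pmax, lapply(seq_len(k), function(ci) cat_lnl[ci, ]))
  m[!is.finite(m)] <- 0
  log(colMeans(exp(cat_lnl - rep(m, each = k)))) + m
}

#' Per-site log-likelihoods under GTR+Gamma
#'
#' Felsenstein pruning over discrete gamma rate categories. IUPAC ambiguity
#' codes (and gaps, treated as fully ambiguous) set the tip conditional
#' likelihood to 1 on every compatible state.
#'
#' @param tree A `phylo` with branch lengths; its tips must all have
#'   sequences in `aln`.
#' @param aln An `rh1_alignment`.
#' @param model An `rh1_model`.
#' @return List with `site_lnl` (per alignment column, natural log),
#'   `total` (sum), `pattern_lnl` and `pattern_weights`.
#' @export
site_log_likelihoods <- function(tree, aln, model) {
  patt <- compress_patterns(aln, taxa = tree$tip.label)
  plnl <- prune_loglik(tree, patt, model)
  list(site_lnl = plnl[patt$map],
       total = sum(plnl * patt$weights),
       pattern_lnl = plnl,
       pattern_weights = patt$weights)
}

#' Total log-likelihood of a tree
#'
#' @inheritParams site_log_likelihoods
#' @return Numeric scalar.
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  patt <- compress_patterns(aln, taxa = tree$tip.label)
  sum(prune_loglik(tree, patt, model) * patt$weights)
}

#' Site log-likelihood matrix for a set of candidate trees
#'
#' The per-site matrix is the input contract of the RELL/AU machinery
#' (see [au_test()]).
#'
#' @param trees List of `phylo` objects (or `multiPhylo`), ideally named.
#' @param aln An `rh1_alignment`.
#' @param models A single `rh1_model` shared by all trees, or a list with one
#'   model per tree.
#' @return Numeric matrix (sites x trees) of natural-log site likelihoods,
#'   with tree labels as colnames.
#' @export
site_loglik_matrix <- function(trees, aln, models) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- length(trees)
  if (inherits(models, "rh1_model")) models <- rep(list(models), n)
  if (length(models) != n) stop("need one model, or one model per tree")
  labels <- names(trees) %||% paste0("tree", seq_len(n))
  out <- matrix(NA_real_, nrow = ncol(aln), ncol = n,
                dimnames = list(NULL, labels))
  for (i in seq_len(n)) {
    out[, i] <- site_log_likelihoods(trees[[i]], aln, models[[i]])$site_lnl
  }
  out
}

#' Write / read a site log-likelihood matrix
#'
#' Plain columnar text: one header line of tree labels, then one row per
#' alignment site.
#'
#' @param mat Sites x trees matrix as produced by [site_loglik_matrix()].
#' @param path File path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_sitelik_matrix <- function(mat, path) {
  df <- as.data.frame(mat)
  write.table(cbind(site = seq_len(nrow(df)), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sitelik_matrix
#' @export
read_sitelik_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as.matrix(df[, -1, drop = FALSE])
}
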