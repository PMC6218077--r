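#' Empirical base frequencies of an alignment
#'
#' @param aln An `rh1_alignment`.
#' @return Frequencies of A, C, G, T among unambiguous bases.
#' @export
empirical_base_freqs <- function(aln) {
  v <- as.vector(unclass(aln))
  counts <- vapply(.nuc_letters, function(b) sum(v == b), numeric(1))
  counts <- pmax(counts, 1)  # guard degenerate alignments
  counts / sum(counts)
}

# Optimise one branch length by bracketed univariate search, expanding a
# local window around the current value until the optimum is interior.
opt_branch <- function(fn, cur, lower = 1e-8, upper = 20, tol = 1e-7) {
  lo <- max(lower, cur / 10)
  hi <- min(upper, max(cur * 10, 0.05))
  for (i in 1:4) {
    res <- optimize(fn, c(lo, hi), maximum = TRUE, tol = tol)
    at_lo <- res$maximum - lo < (hi - lo) * 0.01 && lo > lower
    at_hi <- hi - res$maximum < (hi - lo) * 0.01 && hi < upper
    if (!at_lo && !at_hi) break
    if (at_lo) lo <- max(lower, lo / 20)
    if (at_hi) hi <- min(upper, hi * 20)
  }
  res
}

#' Optimise branch lengths and/or model parameters by coordinate ascent
#'
#' Interleaves bracketed univariate optimisation of each branch length with
#' bounded multivariate (Nelder-Mead, unconstrained transform) steps on the
#' GTR exchangeabilities, base frequencies and gamma shape. The log-likelihood
#' is non-decreasing across sweeps; iteration stops when a full sweep improves
#' it by less than `tol`.
#'
#' @param tree `phylo` with starting branch lengths.
#' @param aln An `rh1_alignment`.
#' @param model Starting `rh1_model`.
#' @param what One of "both", "branch_lengths", "model".
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Maximum number of coordinate-ascent sweeps.
#' @param branch_bounds Lower/upper clamp for branch lengths.
#' @param branch_tol Absolute tolerance of the univariate branch search.
#' @return List with `tree`, `model`, `lnL`, `sweeps`, `converged`.
#' @export
optimize_parameters <- function(tree, aln, model,
                                what = c("both", "branch_lengths", "model"),
                                tol = 1e-4, max_sweeps = 10L,
                                branch_bounds = c(1e-8, 20),
                                branch_tol = 1e-7) {
  what <- match.arg(what)
  patt <- compress_patterns(aln, taxa = tree$tip.label)
  score <- function(tr, mdl) sum(prune_loglik(tr, patt, mdl) * patt$weights)

  do_bl <- what %in% c("both", "branch_lengths")
  do_mod <- what %in% c("both", "model")
  tree$edge.length <- pmin(pmax(tree$edge.length, branch_bounds[1]),
                           branch_bounds[2])
  cur <- score(tree, model)
  start_lnl <- cur
  converged <- FALSE
  sweeps <- 0L

  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    prev <- cur
    if (do_bl) {
      for (e in seq_len(nrow(tree$edge))) {
        fn <- function(b) {
          tr <- tree
          tr$edge.length[e] <- b
          score(tr, model)
        }
        res <- opt_branch(fn, tree$edge.length[e],
                          branch_bounds[1], branch_bounds[2],
                          tol = branch_tol)
        if (res$objective > cur) {
          tree$edge.length[e] <- res$maximum
          cur <- res$objective
        }
      }
    }
    if (do_mod) {
      par0 <- c(log(model$rates[1:5]),
                log(model$base_freqs[1:3] / model$base_freqs[4]),
                log(model$gamma_shape))
      unpack <- function(p) {
        fr <- exp(c(p[6:8], 0))
        update_model(model,
                     rates = c(exp(p[1:5]), 1),
                     base_freqs = fr / sum(fr),
                     gamma_shape = min(exp(p[9]), 100))
      }
      fn <- function(p) {
        if (any(abs(p) > 12)) return(1e10)
        -score(tree, unpack(p))
      }
      opt <- optim(par0, fn, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-9))
      if (-opt$value > cur) {
        model <- unpack(opt$par)
        cur <- -opt$value
      }
    }
    if (cur - prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (cur < start_lnl - tol) {
    stop("optimisation decreased the log-likelihood; this is a bug")
  }
  list(tree = tree, model = model, lnL = cur,
       sweeps = sweeps, converged = converged)
}
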