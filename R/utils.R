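#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim optimize pchisq pgamma qgamma qnorm pnorm dnorm
#'   rmultinom runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# IUPAC nucleotide codes as state sets over (A, C, G, T).
# Gaps and '?' are treated as fully ambiguous (same as N).
.iupac_states <- list(
  A = 1L, C = 2L, G = 3L, T = 4L, U = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), K = c(3L, 4L), M = c(1L, 2L),
  S = c(2L, 3L), W = c(1L, 4L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
  N = 1:4, `-` = 1:4, `?` = 1:4
)

.nuc_letters <- c("A", "C", "G", "T")

# Deterministic derived seed so that independent random streams (e.g. tree
# events vs. sequence evolution) can be driven from one user seed.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(salt)) %% 2147483629) + 1L
}

# 0/1 conditional-likelihood column vectors for one sequence (4 x n matrix).
encode_partials <- function(chars) {
  chars <- toupper(chars)
  out <- matrix(0, nrow = 4L, ncol = length(chars))
  for (i in seq_along(chars)) {
    st <- .iupac_states[[chars[i]]]
    if (is.null(st)) {
      stop("unknown nucleotide code: '", chars[i], "'")
    }
    out[st, i] <- 1
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
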