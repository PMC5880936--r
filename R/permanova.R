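# One-factor PERMANOVA on a distance matrix: pseudo-F from the
# Gower-centred inner-product matrix, p-value by label permutation.

# among-group sum of squares tr(H G H) = sum_g (1/n_g) sum_{i,j in g} G_ij
.ssAmong <- function(G, grouping) {
  ss <- 0
  for (lev in unique(grouping)) {
    idx <- which(grouping == lev)
    ss <- ss + sum(G[idx, idx]) / length(idx)
  }
  ss
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a distance matrix over a single grouping factor following the
#' Gower-centring construction: with `A = -d^2 / 2` and
#' `G = (I - J/n) A (I - J/n)`, the pseudo-F is
#' `[tr(HGH)/(a-1)] / [tr((I-H)G(I-H))/(n-a)]` for the hat matrix `H` of the
#' factor.  Significance is assessed by permuting sample labels;
#' `p = (1 + #{F_perm >= F_obs}) / (1 + permutations)`.
#'
#' @param d symmetric distance matrix.
#' @param grouping factor (or vector) of group labels, one per sample; at
#'   least two groups, each ideally with two or more samples (singleton
#'   groups raise a warning).
#' @param permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return a [PermanovaResult-class].
#' @export
permanovaTest <- function(d, grouping, permutations = 999, seed = NULL) {
  d <- .checkDistanceMatrix(d)
  grouping <- as.character(grouping)
  n <- nrow(d)
  if (length(grouping) != n)
    stop("grouping must have one label per sample")
  sizes <- table(grouping)
  a <- length(sizes)
  if (a < 2) stop("PERMANOVA needs at least two groups")
  if (any(sizes == 1))
    warning("singleton group(s) present: permutation distribution is restricted")
  if (!is.null(seed)) set.seed(seed)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ssT <- sum(diag(G))
  fstat <- function(g) {
    ssA <- .ssAmong(G, g)
    ssR <- ssT - ssA
    if (ssR < 1e-12 * max(ssT, 1)) return(Inf)  # perfect separation
    (ssA / (a - 1)) / (ssR / (n - a))
  }
  fObs <- fstat(grouping)
  ge <- 0L
  for (p in seq_len(permutations))
    if (fstat(sample(grouping)) >= fObs) ge <- ge + 1L
  ssA <- .ssAmong(G, grouping)
  new("PermanovaResult",
      pseudoF = fObs,
      pValue = (1 + ge) / (1 + permutations),
      permutations = as.integer(permutations),
      factorName = "grouping",
      ssAmong = ssA, ssResidual = ssT - ssA,
      df = c(a - 1, n - a))
}
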