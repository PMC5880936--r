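# Non-metric multidimensional scaling by direct minimisation of Kruskal's
# stress-1, alternating monotone (isotonic) regression on the ranked
# dissimilarities with a Guttman-transform configuration update.  A
# step-halving line search guarantees the accepted stress never increases.

.checkDistanceMatrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("input must be a symmetric distance matrix")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix must have a zero diagonal")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  d
}

# isotonic fit of configuration distances against dissimilarity order;
# ties in the dissimilarities are broken by the current distances
# (Kruskal's primary approach)
.stress1 <- function(dvec, deltaOrd) {
  dhat <- numeric(length(dvec))
  dhat[deltaOrd] <- isoreg(dvec[deltaOrd])$yf
  ss <- sum(dvec^2)
  list(stress = if (ss > 0) sqrt(sum((dvec - dhat)^2) / ss) else 0,
       dhat = dhat)
}

.guttman <- function(X, dhat, dmat) {
  n <- nrow(X)
  ratio <- matrix(0, n, n)
  pos <- dmat > 0
  ratio[pos] <- dhat[pos] / dmat[pos]
  B <- -ratio
  diag(B) <- rowSums(ratio)
  B %*% X / n
}

.nmdsFromStart <- function(X, delta, maxit, tol, tolIter) {
  n <- nrow(X)
  low <- lower.tri(delta)
  dvec0 <- delta[low]
  trajectory <- numeric(0)
  stall <- 0L
  converged <- FALSE
  dmat <- as.matrix(dist(X))
  deltaOrd <- order(dvec0, dmat[low])
  st <- .stress1(dmat[low], deltaOrd)
  for (it in seq_len(maxit)) {
    Xc <- .guttman(X, .expandSym(st$dhat, n), dmat)
    step <- 1
    repeat {
      Xt <- X + step * (Xc - X)
      dmatT <- as.matrix(dist(Xt))
      ordT <- order(dvec0, dmatT[low])
      stT <- .stress1(dmatT[low], ordT)
      if (stT$stress <= st$stress || step < 1e-4) break
      step <- step / 2
    }
    improved <- st$stress - stT$stress
    if (stT$stress <= st$stress) {
      X <- Xt; dmat <- dmatT; st <- stT
    }
    trajectory <- c(trajectory, st$stress)
    stall <- if (improved < tol) stall + 1L else 0L
    if (stall >= tolIter) { converged <- TRUE; break }
  }
  list(X = X, stress = st$stress, trajectory = trajectory,
       converged = converged)
}

.expandSym <- function(vec, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vec
  m + t(m)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a distance matrix in `k` dimensions by iterative minimisation of
#' Kruskal's stress-1 with monotone regression on the ranked
#' dissimilarities.  The first start is the classical metric scaling
#' (principal coordinates) solution; the remaining starts jitter it or draw
#' random configurations, and the best final stress is reported.
#'
#' @param d symmetric distance matrix (zero diagonal).
#' @param k number of ordination axes (default 4); must satisfy
#'   `k < n - 1`.
#' @param seed optional integer seed controlling the random restarts.
#' @param nStarts number of starting configurations (default 20).
#' @param maxit maximum iterations per start.
#' @param tol convergence: stress improvement below `tol` for `tolIter`
#'   consecutive iterations.
#' @param tolIter see `tol`.
#' @return an [NmdsResult-class].
#' @export
nmdsOrdination <- function(d, k = 4, seed = NULL, nStarts = 20, maxit = 200,
                           tol = 1e-6, tolIter = 10) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (k > n - 1) stop("k must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  X0 <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(X0) < k)            # rank-deficient PCoA: pad with tiny noise
    X0 <- cbind(X0, matrix(rnorm(n * (k - ncol(X0)), sd = 1e-4), n))
  scale0 <- max(sqrt(rowSums(X0^2)), 1e-8)
  best <- NULL
  for (s in seq_len(nStarts)) {
    X <- if (s == 1) X0
         else if (s %% 2 == 0) X0 + matrix(rnorm(n * k, sd = 0.1 * scale0), n)
         else matrix(rnorm(n * k, sd = scale0), n)
    fit <- .nmdsFromStart(X, d, maxit, tol, tolIter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$X
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("MDS", seq_len(k))
  new("NmdsResult", points = pts, stress = best$stress, k = as.integer(k),
      converged = best$converged, trajectory = best$trajectory,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
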