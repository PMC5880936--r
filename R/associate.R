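# Spearman taxa-environment association screening with Benjamini-Hochberg
# step-up control of the false discovery rate.

# average ranks (midranks) for ties
.avgRank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of average (midrank) ranks.  For n <= 9
#' with untied data the p-value comes from the exact permutation null
#' distribution of rho; otherwise the usual t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df is used.  Constant input
#' gives `rho = NA`.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return list with `rho` and `p`.
#' @export
spearmanTest <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Spearman association needs at least 4 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- .avgRank(x); ry <- .avgRank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' With order statistics `p_(1) <= ... <= p_(m)`, the adjusted value of
#' `p_(i)` is `min_{j >= i} min(m p_(j) / j, 1)`, which makes the adjusted
#' vector monotone in the raw one and never smaller than it.
#'
#' @param p vector of raw p-values (NAs passed through).
#' @return adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  po <- p[ok]
  o <- order(po, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * po[o]))
  out[ok][o] <- adj
  out
}

#' Taxa-environment association screen
#'
#' Correlates every (taxon, environmental variable) pair by Spearman's
#' method and adjusts the full p-value matrix by the Benjamini-Hochberg
#' step-up procedure (`scope = "matrix"`, the default) or within each
#' variable (`scope = "variable"`).  Pairs with adjusted p below `alpha`
#' are flagged significant; `alpha` applied to the raw p-values is exposed
#' via `useRaw = TRUE`.
#'
#' @param taxa samples x taxa matrix/data.frame of (relative) abundances,
#'   typically the dominant taxa (> 1%).
#' @param env samples x variables matrix/data.frame of endpoint chemistry.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param scope `"matrix"` or `"variable"` BH adjustment scope.
#' @param useRaw flag significance on raw instead of adjusted p-values.
#' @return `data.frame` with `taxon`, `variable`, `rho`, `p`, `p_adj`,
#'   `significant`.
#' @export
associateTaxa <- function(taxa, env, alpha = 0.05,
                          scope = c("matrix", "variable"), useRaw = FALSE) {
  scope <- match.arg(scope)
  taxa <- as.matrix(taxa); env <- as.matrix(env)
  if (nrow(taxa) != nrow(env))
    stop("taxa and env must describe the same samples (rows)")
  if (nrow(taxa) < 4)
    stop("Spearman association needs at least 4 paired observations")
  grid <- expand.grid(taxon = colnames(taxa), variable = colnames(env),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(tx, vb) {
    unlist(spearmanTest(taxa[, tx], env[, vb]))
  }, grid$taxon, grid$variable)
  grid$rho <- res["rho", ]
  grid$p <- res["p", ]
  if (scope == "matrix") {
    grid$p_adj <- bhAdjust(grid$p)
  } else {
    grid$p_adj <- NA_real_
    for (vb in unique(grid$variable)) {
      idx <- grid$variable == vb
      grid$p_adj[idx] <- bhAdjust(grid$p[idx])
    }
  }
  grid$significant <- !is.na(grid$p_adj) &
    (if (useRaw) grid$p else grid$p_adj) < alpha
  rownames(grid) <- NULL
  grid
}
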