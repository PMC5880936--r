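# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# tips descending from a node, by naive recursion over the edge list
.tipsBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tipsBelow, tree = tree))
}

# direct per-branch evaluation of the generalized UniFrac formula
oracleGUniFrac <- function(counts, tree, alpha) {
  props <- sweep(counts, 2, colSums(counts), "/")
  n <- ncol(counts)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- .tipsBelow(tree, tree$edge[e, 2])
      tips <- intersect(tips, rownames(counts))
      pa <- sum(props[tips, i]); pb <- sum(props[tips, j])
      if (pa + pb == 0) next
      w <- tree$edge.length[e] * (pa + pb)^alpha
      num <- num + w * abs(pa - pb) / (pa + pb)
      den <- den + w
    }
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  d
}

# weighted normalized UniFrac: sum l |pA-pB| / sum l (pA+pB)
oracleWeightedUniFrac <- function(counts, tree) {
  props <- sweep(counts, 2, colSums(counts), "/")
  n <- ncol(counts)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- intersect(.tipsBelow(tree, tree$edge[e, 2]), rownames(counts))
      pa <- sum(props[tips, i]); pb <- sum(props[tips, j])
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  d
}

# random rooted tree + matched count matrix
randomCountTree <- function(nLeaf, nSamp, maxCount = 30) {
  tree <- ape::rtree(nLeaf, br = function(n) rexp(n))
  counts <- matrix(sample(0:maxCount, nLeaf * nSamp, replace = TRUE),
                   nLeaf, nSamp,
                   dimnames = list(tree$tip.label, paste0("s", seq_len(nSamp))))
  for (s in seq_len(nSamp))
    if (sum(counts[, s]) == 0) counts[sample(nLeaf, 1), s] <- 1
  list(tree = tree, counts = counts)
}

# all-pairs Welch-free t comparison via TukeyHSD on a fresh aov fit,
# used to check the compact letter display from first principles
tukeyPairwiseP <- function(values, groups) {
  fit <- stats::aov(values ~ factor(groups))
  tk <- stats::TukeyHSD(fit)[[1]]
  lv <- levels(factor(groups))
  pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(prs))
    pmat[prs[[r]][1], prs[[r]][2]] <- pmat[prs[[r]][2], prs[[r]][1]] <-
      tk[r, "p adj"]
  pmat
}
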