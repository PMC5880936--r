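# Generalized UniFrac distances over a rooted, branch-length tree.

# branch (edge) x sample matrix of subtended relative abundances, computed
# by a single postorder accumulation over the edge matrix
.branchProportions <- function(props, tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  cum <- matrix(0, ntip + nnode, ncol(props))
  idx <- match(tree$tip.label, rownames(props))
  hit <- !is.na(idx)
  cum[which(hit), ] <- props[idx[hit], , drop = FALSE]
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge)))
    cum[edge[e, 1], ] <- cum[edge[e, 1], ] + cum[edge[e, 2], ]
  # proportions subtended by each edge, in the tree's native edge order
  cum[tree$edge[, 2], , drop = FALSE]
}

#' Generalized UniFrac distance matrix
#'
#' Phylogenetic beta diversity of the generalized UniFrac family with
#' moderation parameter `alpha` in `[0, 1]`: for samples A and B,
#' \deqn{d(A,B) = \frac{\sum_b \ell_b (p_A + p_B)^\alpha \, |p_A - p_B| /
#'   (p_A + p_B)}{\sum_b \ell_b (p_A + p_B)^\alpha}}
#' where the sums run over tree branches `b` of length `l_b` and `p` is the
#' relative abundance subtended by the branch.  Branches with no reads in
#' either sample contribute nothing; `alpha = 1` recovers the weighted
#' normalized UniFrac distance.  Proportions are per-sample total-count
#' normalized (no rarefaction).
#'
#' @param x an [OtuExperiment-class] carrying a tree, or an OTU x sample
#'   count matrix (rownames = OTU ids).
#' @param tree rooted `phylo` with branch lengths; taken from `x` when it is
#'   an `OtuExperiment`.
#' @param alpha abundance-moderation parameter, default 0.5.
#' @return symmetric distance matrix with zero diagonal, entries in `[0, 1]`.
#' @examples
#' tr <- ape::read.tree(text = "(a:1,b:1);")
#' m <- cbind(A = c(a = 10, b = 0), B = c(a = 0, b = 10))
#' generalizedUniFrac(m, tr, alpha = 0.5)   # maximally distinct: 1
#' @export
generalizedUniFrac <- function(x, tree = NULL, alpha = 0.5) {
  if (is(x, "OtuExperiment")) {
    if (is.null(tree)) tree <- otuTree(x)
    x <- otuCounts(x)
  }
  counts <- as.matrix(x)
  if (is.null(tree)) stop("a rooted tree with branch lengths is required")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (is.null(rownames(counts)))
    stop("count matrix must carry OTU ids as rownames")
  off <- setdiff(rownames(counts), tree$tip.label)
  if (length(off))
    stop("OTUs missing from the tree: ", paste(off, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- colSums(counts)
  if (any(depth == 0)) stop("all-zero samples cannot be placed in UniFrac space")
  props <- sweep(counts, 2, depth, "/")
  B <- .branchProportions(props, tree)
  len <- tree$edge.length
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pa <- B[, i]; pb <- B[, j]
    tot <- pa + pb
    sel <- tot > 0
    w <- len[sel] * tot[sel]^alpha
    den <- sum(w)
    d[i, j] <- d[j, i] <-
      if (den > 0) sum(w * abs(pa[sel] - pb[sel]) / tot[sel]) / den else 0
  }
  d
}
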