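# Abundance-based alpha-diversity estimators computed per sample.

.alphaOne <- function(x, rareCutoff = 10) {
  x <- x[x > 0]
  if (length(x) == 0L) stop("empty sample: alpha diversity undefined")
  n <- sum(x)
  p <- x / n
  sObs <- length(x)
  shannon <- -sum(p * log(p))
  simpson <- 1 - sum(p^2)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  chao1 <- if (f2 > 0) sObs + f1^2 / (2 * f2)
           else sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
  ## ACE with the standard rare-abundance cutoff (counts <= 10)
  rare <- x[x <= rareCutoff]
  sRare <- length(rare); sAbund <- sObs - sRare
  nRare <- sum(rare)
  if (sRare == 0L || nRare == 0L) {
    ace <- sObs
  } else {
    cAce <- 1 - f1 / nRare
    if (cAce <= 0) {
      ace <- chao1      # all rare counts are singletons; ACE undefined
    } else {
      fi <- tabulate(rare, nbins = rareCutoff)
      gamma2 <- max(sRare / cAce *
                      sum(seq_len(rareCutoff) * (seq_len(rareCutoff) - 1) * fi) /
                      (nRare * (nRare - 1)) - 1, 0)
      ace <- sAbund + sRare / cAce + f1 / cAce * gamma2
    }
  }
  c(observed = sObs, ace = ace, chao1 = chao1, simpson = simpson,
    shannon = shannon)
}

#' Alpha-diversity indices per sample
#'
#' Computes, for every sample of an OTU table, observed richness and the
#' ACE, Chao1, Gini-Simpson (`1 - sum p_i^2`) and Shannon (`-sum p_i ln p_i`)
#' indices.  Chao1 uses the classic singleton/doubleton estimator
#' `S_obs + F1^2 / (2 F2)`, switching to the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when no doubletons are present;
#' ACE uses the standard rare-abundance cutoff of 10 reads.
#'
#' @param x an [OtuExperiment-class] or an OTU x sample count matrix.
#' @param rareCutoff rare-species count cutoff for ACE.
#' @return a `data.frame`, one row per sample, columns `sample_id`,
#'   `observed`, `ace`, `chao1`, `simpson`, `shannon`.
#' @examples
#' m <- cbind(s1 = c(25, 25, 25, 25), s2 = c(100, 0, 0, 0))
#' alphaDiversity(m)
#' @export
alphaDiversity <- function(x, rareCutoff = 10) {
  counts <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (any(colSums(counts) == 0)) stop("empty sample: alpha diversity undefined")
  res <- t(apply(counts, 2, .alphaOne, rareCutoff = rareCutoff))
  data.frame(sample_id = colnames(counts), res,
             row.names = NULL, stringsAsFactors = FALSE)
}
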