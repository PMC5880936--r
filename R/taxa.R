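# Aggregation of OTU counts to a taxonomic rank with a dominance threshold.

.TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

# parse semicolon-ranked lineage strings into a rank data.frame
.parseLineages <- function(lineages, ranks = .TAX_RANKS) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  out <- matrix(NA_character_, length(lineages), length(ranks),
                dimnames = list(NULL, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-z]__", "", p)          # tolerate QIIME-style prefixes
    p[p == ""] <- NA_character_
    out[i, seq_len(min(length(p), length(ranks)))] <-
      p[seq_len(min(length(p), length(ranks)))]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts over all OTUs sharing a lineage at `rank`, computes per-sample
#' relative abundances, and pools every lineage whose across-sample mean
#' relative abundance does not exceed `minMeanRelAbund` into an `"other"`
#' bin, following the usual dominant-taxa barplot convention (e.g. families
#' above 2%, genera above 1%).  OTUs without a label at `rank` are assigned
#' `unclassified_<parent>` from the nearest labelled parent rank.
#'
#' @param x an [OtuExperiment-class] with taxonomy in `rowData`, or a count
#'   matrix plus a `taxonomy` argument.
#' @param rank rank to aggregate at (one of kingdom...genus, or the name of
#'   a taxonomy column).
#' @param minMeanRelAbund dominance threshold on the mean relative
#'   abundance; 0 keeps every lineage.
#' @param taxonomy `data.frame` of rank columns, or character vector of
#'   semicolon-ranked lineages (needed when `x` is a matrix).
#' @return list with `counts` (lineage x sample), `relAbundance`
#'   (columns sum to 1) and `kept` (lineages above the threshold).
#' @export
aggregateTaxa <- function(x, rank = "family", minMeanRelAbund = 0.02,
                          taxonomy = NULL) {
  if (is(x, "OtuExperiment")) {
    if (is.null(taxonomy)) taxonomy <- taxonomyTable(x)
    x <- otuCounts(x)
  }
  counts <- as.matrix(x)
  if (is.null(taxonomy) || (is.data.frame(taxonomy) && ncol(taxonomy) == 0L))
    stop("taxonomy is required for aggregation")
  if (is.character(taxonomy)) taxonomy <- .parseLineages(taxonomy)
  if (!rank %in% names(taxonomy))
    stop(sprintf("rank '%s' not present in the taxonomy", rank))
  lab <- as.character(taxonomy[[rank]])
  ## unlabelled ranks: name after the nearest labelled parent
  ri <- match(rank, names(taxonomy))
  for (i in which(is.na(lab) | lab == "")) {
    parent <- "root"
    if (ri > 1) {
      up <- rev(as.character(unlist(taxonomy[i, seq_len(ri - 1)])))
      up <- up[!is.na(up) & up != ""]
      if (length(up)) parent <- up[1]
    }
    lab[i] <- paste0("unclassified_", parent)
  }
  agg <- rowsum(counts, lab)
  rel <- sweep(agg, 2, colSums(agg), "/")
  keep <- rowMeans(rel) > minMeanRelAbund
  kept <- rownames(agg)[keep]
  if (!all(keep)) {
    other <- colSums(agg[!keep, , drop = FALSE])
    agg <- rbind(agg[keep, , drop = FALSE], other = other)
  }
  rel <- sweep(agg, 2, colSums(agg), "/")
  list(counts = agg, relAbundance = rel, kept = kept)
}
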