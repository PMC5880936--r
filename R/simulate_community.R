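# Dirichlet-multinomial community simulator with treatment effects on
# designated taxa, a random bifurcating tree and family-level taxonomy.

#' Default community simulation configuration
#'
#' Baseline family proportions loosely shaped like an anaerobic flooded-soil
#' bacterial community (sulfate reducers, fermenters, dechlorinators), with
#' multiplicative treatment effects on designated families: biochar strongly
#' enriches SB-1 and the sulfate reducers Desulfobulbaceae /
#' Desulfobacteraceae, AQDS enriches Desulforudaceae, molybdate collapses
#' the sulfate reducers and favours Clostridiaceae / Dehalobacteriaceae.
#'
#' @param nOtus number of OTUs (default 120).
#' @param nReplicates samples per biotic treatment (default 3; 6 treatments).
#' @param depth reads per sample (default 5000).
#' @param theta Dirichlet concentration mass controlling overdispersion
#'   (default 500, calibrated so the 18-sample preset ordination reaches the
#'   reported stress range of ~0.03-0.04; larger = closer to multinomial).
#' @return a list config understood by [simulateCommunity()]: elements
#'   `nOtus`, `nReplicates`, `depth`, `theta`, `baseFamilies` (named
#'   proportions), `effects` (per-amendment and molybdate fold-changes on
#'   families).
#' @export
communityConfig <- function(nOtus = 120, nReplicates = 3, depth = 5000,
                            theta = 500) {
  baseFamilies <- c(
    Desulforudaceae = 0.250, Clostridiaceae = 0.170, Peptococcaceae = 0.100,
    `SB-1` = 0.045, Spirochaetaceae = 0.035, Desulfobulbaceae = 0.030,
    Desulfobacteraceae = 0.030, Pelobacteraceae = 0.020,
    Dehalobacteriaceae = 0.020, Pseudomonadaceae = 0.030,
    Halomonadaceae = 0.020, Ruminococcaceae = 0.060, Bacteroidaceae = 0.080,
    Porphyromonadaceae = 0.050, Geobacteraceae = 0.030, Rhodocyclaceae = 0.030)
  stopifnot(abs(sum(baseFamilies) - 1) < 1e-9)
  effects <- list(
    amendment = list(
      control = c(),
      AQDS = c(Desulforudaceae = 1.8, Pseudomonadaceae = 1.6,
               Halomonadaceae = 1.6, Pelobacteraceae = 1.6,
               Clostridiaceae = 0.5),
      biochar = c(`SB-1` = 6, Desulfobulbaceae = 2.2, Desulfobacteraceae = 2.2,
                  Pelobacteraceae = 2, Dehalobacteriaceae = 1.6,
                  Clostridiaceae = 0.5, Peptococcaceae = 0.5)),
    molybdate = c(Desulfobulbaceae = 0.05, Desulfobacteraceae = 0.05,
                  Desulforudaceae = 0.5, Peptococcaceae = 0.5,
                  Spirochaetaceae = 0.5, Clostridiaceae = 1.6,
                  Dehalobacteriaceae = 1.6, Pseudomonadaceae = 1.5,
                  Halomonadaceae = 1.5))
  list(nOtus = nOtus, nReplicates = nReplicates, depth = depth, theta = theta,
       baseFamilies = baseFamilies, effects = effects)
}

.applyFold <- function(p, families, fold) {
  if (length(fold) == 0L) return(p)
  off <- setdiff(names(fold), families)
  if (length(off))
    stop("effect on unknown taxon: ", paste(off, collapse = ", "))
  for (fam in names(fold))
    p[families == fam] <- p[families == fam] * fold[[fam]]
  p / sum(p)
}

#' Simulate an OTU table, tree and metadata for the biotic design
#'
#' Draws Dirichlet-multinomial counts for the six biotic treatments
#' (with/without molybdate x control/AQDS/biochar, `nReplicates` samples
#' each).  Baseline family proportions are split across member OTUs by a
#' flat Dirichlet; treatment fold-changes multiply the designated families
#' before renormalisation; each sample then draws OTU proportions from
#' `Dirichlet(p * theta)` and counts from `Multinomial(depth)`.  The
#' phylogeny is a random bifurcating tree with exponential branch lengths
#' over the OTUs.
#'
#' @param seed integer seed.
#' @param config list from [communityConfig()].
#' @return an [OtuExperiment-class] with counts, taxonomy (`family`
#'   column), sample metadata (`group`, `amendment`, `replicate`,
#'   `treatment`) and the tree.
#' @examples
#' oe <- simulateCommunity(seed = 1, config = communityConfig(nOtus = 40))
#' oe
#' @export
simulateCommunity <- function(seed = 1, config = communityConfig()) {
  set.seed(seed)
  nOtus <- config$nOtus
  fams <- names(config$baseFamilies)
  # at least one OTU per family, remainder proportional to family mass
  alloc <- rep(1L, length(fams))
  extra <- nOtus - length(fams)
  if (extra < 0) stop("nOtus must be at least the number of families")
  if (extra > 0) {
    add <- table(factor(sample(fams, extra, replace = TRUE,
                               prob = config$baseFamilies), levels = fams))
    alloc <- alloc + as.integer(add)
  }
  family <- rep(fams, alloc)
  otuIds <- sprintf("OTU%04d", seq_len(nOtus))
  # split each family's mass across its OTUs with a flat Dirichlet
  base <- numeric(nOtus)
  for (fam in fams) {
    idx <- which(family == fam)
    w <- rgamma(length(idx), shape = 1)
    base[idx] <- config$baseFamilies[[fam]] * w / sum(w)
  }
  design <- expand.grid(replicate = seq_len(config$nReplicates),
                        amendment = .AMENDMENTS,
                        group = c("biotic", "biotic_molybdate"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("group", "amendment", "replicate")]
  design$treatment <- paste0(ifelse(design$group == "biotic_molybdate",
                                    "M-", ""),
                             c(control = "CK", AQDS = "A",
                               biochar = "B")[design$amendment])
  counts <- matrix(0L, nOtus, nrow(design),
                   dimnames = list(otuIds, paste0(design$treatment, "_",
                                                  design$replicate)))
  for (s in seq_len(nrow(design))) {
    p <- .applyFold(base, family,
                    config$effects$amendment[[design$amendment[s]]])
    if (design$group[s] == "biotic_molybdate")
      p <- .applyFold(p, family, config$effects$molybdate)
    g <- rgamma(nOtus, shape = p * config$theta)
    if (sum(g) == 0) g <- p
    counts[, s] <- rmultinom(1, config$depth, g / sum(g))
  }
  tree <- ape::rtree(nOtus, tip.label = otuIds,
                     br = function(n) rexp(n, rate = 10))
  taxonomy <- data.frame(kingdom = "Bacteria", family = family,
                         row.names = otuIds, stringsAsFactors = FALSE)
  otuExperiment(counts, taxonomy = taxonomy, tree = tree,
                sampleData = design)
}
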