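#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov TukeyHSD anova lm sd cmdscale dist isoreg rnorm
#'   rgamma rmultinom rlnorm runif cor pt setNames complete.cases
#' @importFrom utils read.table write.table read.csv write.csv packageVersion
NULL

setOldClass("phylo")

#' Balanced half reaction of a terminal electron acceptor
#'
#' One redox couple of the anaerobic ladder, together with the number of
#' electron equivalents transferred per mole of compound (eeq/mol).  The
#' `electrons` slot holds the electrons appearing in the written half
#' reaction (zero for the acetoclastic methane disproportionation, whose
#' 8 eeq/mol is stoichiometric bookkeeping); `eeqPerMol` is the value used
#' by the electron ledger.
#'
#' @slot name registry key, e.g. `"ferrous_iron"`.
#' @slot oxidizedSpecies,reducedSpecies chemical formulae of the couple.
#' @slot eeqPerMol electron equivalents per mole of compound.
#' @slot electrons electrons in the written half reaction.
#' @slot protons protons consumed in the written half reaction.
#' @slot oxidizedCharge,reducedCharge summed ionic charge of each side,
#'   excluding protons and electrons; used by the validity method to check
#'   charge balance.
#' @slot referenceNote free-text provenance note.
#' @export
setClass("HalfReaction",
  representation(
    name = "character",
    oxidizedSpecies = "character",
    reducedSpecies = "character",
    eeqPerMol = "integer",
    electrons = "integer",
    protons = "integer",
    oxidizedCharge = "numeric",
    reducedCharge = "numeric",
    referenceNote = "character"
  )
)

setValidity("HalfReaction", function(object) {
  msg <- character()
  if (object@eeqPerMol < 1L)
    msg <- c(msg, "eeqPerMol must be >= 1")
  ## charge balance: ox side charge + protons - electrons == reduced side
  bal <- object@oxidizedCharge + object@protons - object@electrons
  if (abs(bal - object@reducedCharge) > 1e-9)
    msg <- c(msg, sprintf("half reaction '%s' is not charge balanced (%g != %g)",
                          object@name, bal, object@reducedCharge))
  if (length(msg)) msg else TRUE
})

setMethod("show", "HalfReaction", function(object) {
  cat(sprintf("HalfReaction '%s': %s -> %s  (%d eeq/mol)\n",
              object@name, object@oxidizedSpecies, object@reducedSpecies,
              object@eeqPerMol))
})

#' Serum-bottle geometry of an anaerobic incubation
#'
#' Defaults describe a 150 mL serum bottle with 15 g air-dry soil flooded by
#' 30 mL water and a calibrated headspace gas basis of 1000 umol total gas,
#' so 1 permil of headspace methane corresponds to 1 umol CH4.
#'
#' @slot soilMass g air-dry soil per bottle.
#' @slot waterVolume mL water added.
#' @slot bottleVolume mL total bottle volume.
#' @slot headspaceGasBasis umol total headspace gas used to convert permil
#'   readings to moles; a calibration constant, not a physical gas amount.
#' @slot temperature incubation temperature, degrees C.
#' @export
setClass("BottleGeometry",
  representation(
    soilMass = "numeric",
    waterVolume = "numeric",
    bottleVolume = "numeric",
    headspaceGasBasis = "numeric",
    temperature = "numeric"
  ),
  prototype(soilMass = 15, waterVolume = 30, bottleVolume = 150,
            headspaceGasBasis = 1000, temperature = 25)
)

setValidity("BottleGeometry", function(object) {
  msg <- character()
  vals <- c(soilMass = object@soilMass, waterVolume = object@waterVolume,
            bottleVolume = object@bottleVolume,
            headspaceGasBasis = object@headspaceGasBasis)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    msg <- c(msg, paste("slots must be positive:", paste(bad, collapse = ", ")))
  if (object@waterVolume >= object@bottleVolume)
    msg <- c(msg, "waterVolume must be smaller than bottleVolume")
  if (length(msg)) msg else TRUE
})

#' @describeIn BottleGeometry-class constructor.
#' @param soilMass,waterVolume,bottleVolume,headspaceGasBasis,temperature see
#'   the corresponding slots.
#' @return a validated `BottleGeometry` object.
#' @examples
#' bottleGeometry()                 # the default 15 g / 30 mL / 150 mL bottle
#' bottleGeometry(soilMass = 10)
#' @export
bottleGeometry <- function(soilMass = 15, waterVolume = 30, bottleVolume = 150,
                           headspaceGasBasis = 1000, temperature = 25) {
  new("BottleGeometry", soilMass = soilMass, waterVolume = waterVolume,
      bottleVolume = bottleVolume, headspaceGasBasis = headspaceGasBasis,
      temperature = temperature)
}

setMethod("show", "BottleGeometry", function(object) {
  cat(sprintf(paste0("BottleGeometry: %g g soil, %g mL water in %g mL bottle, ",
                     "gas basis %g umol, %g degC\n"),
              object@soilMass, object@waterVolume, object@bottleVolume,
              object@headspaceGasBasis, object@temperature))
})

#' OTU count container with an optional rooted phylogeny
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `tree` slot
#' holding an [ape::read.tree()]-style `phylo` object whose tips cover the
#' OTUs of the `counts` assay.  Taxonomy lives in `rowData`, sample metadata
#' (treatment group, amendment, replicate) in `colData`.
#'
#' @slot tree a rooted `phylo` object with branch lengths, or `NULL`.
#' @export
setClass("OtuExperiment",
  contains = "SummarizedExperiment",
  representation(tree = "ANY"),
  prototype(tree = NULL)
)

setValidity("OtuExperiment", function(object) {
  msg <- character()
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts must be integral")
  if (ncol(cts) && any(colSums(cts) == 0))
    msg <- c(msg, "all-zero samples are not allowed")
  tr <- object@tree
  if (!is.null(tr)) {
    if (!inherits(tr, "phylo")) {
      msg <- c(msg, "tree must be a 'phylo' object or NULL")
    } else {
      missing <- setdiff(rownames(object), tr$tip.label)
      if (length(missing))
        msg <- c(msg, paste("OTUs absent from the tree:",
                            paste(utils::head(missing, 5), collapse = ", ")))
      if (is.null(tr$edge.length))
        msg <- c(msg, "tree must carry branch lengths")
      if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OtuExperiment-class constructor.
#' @param counts integer matrix, OTUs in rows and samples in columns.
#' @param taxonomy optional `data.frame` of ranked lineages, one row per OTU.
#' @param tree optional rooted `phylo` covering the OTUs.
#' @param sampleData optional `data.frame` of per-sample metadata.
#' @return an `OtuExperiment`.
#' @export
otuExperiment <- function(counts, taxonomy = NULL, tree = NULL,
                          sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  rd <- if (is.null(taxonomy)) S4Vectors::DataFrame(row.names = rownames(counts))
        else S4Vectors::DataFrame(taxonomy, row.names = rownames(counts))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("OtuExperiment", se, tree = tree)
}

#' @describeIn OtuExperiment-class the OTU x sample count matrix.
#' @param x an `OtuExperiment`.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn OtuExperiment-class the phylogeny (`phylo` or `NULL`).
#' @export
otuTree <- function(x) x@tree

#' @describeIn OtuExperiment-class taxonomy table as a plain `data.frame`.
#' @export
taxonomyTable <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

setMethod("show", "OtuExperiment", function(object) {
  callNextMethod()
  if (is.null(object@tree)) {
    cat("tree: none\n")
  } else {
    cat(sprintf("tree: rooted, %d tips\n", length(object@tree$tip.label)))
  }
})

#' Result of a non-metric multidimensional scaling fit
#'
#' @slot points samples x k configuration matrix of the best start.
#' @slot stress final Kruskal stress-1 in `[0, 1]`.
#' @slot k number of ordination axes.
#' @slot converged whether the stress improvement criterion was met.
#' @slot trajectory accepted stress value after every iteration of the best
#'   start; non-increasing by construction.
#' @slot seed the seed used for the random restarts (NA if none set).
#' @export
setClass("NmdsResult",
  representation(points = "matrix", stress = "numeric", k = "integer",
                 converged = "logical", trajectory = "numeric",
                 seed = "numeric")
)

setValidity("NmdsResult", function(object) {
  msg <- character()
  if (object@stress < 0 || object@stress > 1)
    msg <- c(msg, "stress must lie in [0, 1]")
  if (ncol(object@points) != object@k)
    msg <- c(msg, "points must have k columns")
  if (length(object@trajectory) > 1 &&
      any(diff(object@trajectory) > 1e-8))
    msg <- c(msg, "stress trajectory must be non-increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NmdsResult", function(object) {
  cat(sprintf("NMDS: %d samples, %d axes, stress-1 = %.4f (%s)\n",
              nrow(object@points), object@k, object@stress,
              if (object@converged) "converged" else "not converged"))
})

#' @describeIn NmdsResult-class ordination coordinates.
#' @param x an `NmdsResult`.
#' @export
nmdsPoints <- function(x) x@points

#' @describeIn NmdsResult-class final Kruskal stress-1.
#' @export
nmdsStress <- function(x) x@stress

#' Result of a permutational multivariate analysis of variance
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot pValue permutation p-value, `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#' @slot permutations number of label permutations.
#' @slot factorName name of the tested grouping factor.
#' @slot ssAmong,ssResidual among-group and residual sums of squares of the
#'   Gower-centred inner-product matrix.
#' @slot df degrees of freedom, `c(among, residual)`.
#' @export
setClass("PermanovaResult",
  representation(pseudoF = "numeric", pValue = "numeric",
                 permutations = "integer", factorName = "character",
                 ssAmong = "numeric", ssResidual = "numeric", df = "numeric")
)

setValidity("PermanovaResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    "pValue must lie in (0, 1]" else TRUE
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.3f, df = (%g, %g), p = %.4g [%d permutations]\n",
              object@factorName, object@pseudoF, object@df[1], object@df[2],
              object@pValue, object@permutations))
})

#' @describeIn PermanovaResult-class observed pseudo-F.
#' @param x a `PermanovaResult`.
#' @export
permanovaF <- function(x) x@pseudoF

#' @describeIn PermanovaResult-class permutation p-value.
#' @export
permanovaP <- function(x) x@pValue
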