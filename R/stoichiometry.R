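# Half-reaction registry, chlorophenol ladder and unit conversions from
# measured endpoint concentrations to per-bottle micromoles.

.registryCache <- new.env(parent = emptyenv())

## IUPAC molar masses, g/mol
.MOLAR_MASS <- c(Fe = 55.845, SO4 = 96.06, CH4 = 16.04,
                 PCP = 266.34, TeCP_2345 = 231.89, TCP_345 = 197.45,
                 DCP_35 = 163.00)

#' Molar masses used by the package
#'
#' Fixed IUPAC molar masses (g/mol) for iron, sulfate, methane and the
#' chlorophenol dechlorination ladder.
#'
#' @return a named numeric vector.
#' @export
molarMasses <- function() .MOLAR_MASS

#' Chlorophenol dechlorination ladder
#'
#' Pentachlorophenol and its sequential reductive dechlorination products;
#' each step replaces one ring chlorine with hydrogen and consumes two
#' electrons, so molar mass drops by ~34.44 g/mol per step.
#'
#' @return a `data.frame` with columns `species`, `chlorines`, `molarMass`,
#'   ordered PCP, 2,3,4,5-TeCP, 3,4,5-TCP, 3,5-DCP.
#' @examples
#' chlorophenolLadder()
#' @export
chlorophenolLadder <- function() {
  data.frame(
    species = c("PCP", "TeCP_2345", "TCP_345", "DCP_35"),
    chlorines = c(5L, 4L, 3L, 2L),
    molarMass = unname(.MOLAR_MASS[c("PCP", "TeCP_2345", "TCP_345", "DCP_35")]),
    stringsAsFactors = FALSE
  )
}

#' Load the half-reaction registry
#'
#' Reads the YAML registry of terminal-electron-acceptor half reactions
#' shipped with the package (or a user-supplied file in the same layout),
#' validates each entry (including machine charge-balance checking) and
#' returns it as a named list of [HalfReaction-class] objects.
#'
#' @param path path to a registry YAML; defaults to the built-in registry
#'   covering Fe(III)/Fe(II), sulfate/sulfide, both methanogenesis routes and
#'   the chlorophenol couples.
#' @return named list of `HalfReaction` objects.
#' @examples
#' names(halfReactionRegistry())
#' @export
halfReactionRegistry <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    if (!is.null(.registryCache$builtin)) return(.registryCache$builtin)
    path <- system.file("extdata", "half_reactions.yaml",
                        package = "redoxbudget", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$couples)) stop("registry file has no 'couples' section")
  reg <- lapply(names(raw$couples), function(nm) {
    e <- raw$couples[[nm]]
    new("HalfReaction", name = nm,
        oxidizedSpecies = e$oxidized_species,
        reducedSpecies = e$reduced_species,
        eeqPerMol = as.integer(e$eeq_per_mol),
        electrons = as.integer(e$electrons),
        protons = as.integer(e$protons),
        oxidizedCharge = as.numeric(e$oxidized_charge),
        reducedCharge = as.numeric(e$reduced_charge),
        referenceNote = if (is.null(e$note)) "" else e$note)
  })
  names(reg) <- names(raw$couples)
  if (builtin) .registryCache$builtin <- reg
  reg
}

#' Electron equivalents per mole for a registered redox couple
#'
#' @param couple registry key, one of
#'   `ferrous_iron`, `sulfide`, `methane_acetoclastic`,
#'   `methane_hydrogenotrophic`, `TeCP`, `TCP`, `DCP`.
#' @param registry registry list, see [halfReactionRegistry()].
#' @return integer eeq/mol.
#' @examples
#' eeqPerMol("ferrous_iron")   # 1
#' eeqPerMol("sulfide")        # 8
#' eeqPerMol("TCP")            # 4
#' @export
eeqPerMol <- function(couple, registry = halfReactionRegistry()) {
  stopifnot(is.character(couple), length(couple) == 1L)
  if (!couple %in% names(registry))
    stop(sprintf("unknown redox couple '%s'; registry has: %s", couple,
                 paste(names(registry), collapse = ", ")))
  registry[[couple]]@eeqPerMol
}

.clCount <- function(species) {
  ladder <- chlorophenolLadder()
  i <- match(species, ladder$species)
  if (any(is.na(i)))
    stop(sprintf("unknown chlorophenol species '%s'",
                 paste(species[is.na(i)], collapse = ", ")))
  ladder$chlorines[i]
}

#' Electron equivalents of a dechlorination step
#'
#' Each Cl-for-H substitution consumes two electrons, so a hop down the
#' ladder from `from` to `to` transfers `2 * (Cl(from) - Cl(to))` electron
#' equivalents per mole.
#'
#' @param from,to species names from [chlorophenolLadder()]
#'   (`"PCP"`, `"TeCP_2345"`, `"TCP_345"`, `"DCP_35"`).
#' @return integer eeq/mol.
#' @examples
#' dechlorinationEeq("PCP", "TeCP_2345")  # 2
#' dechlorinationEeq("PCP", "TCP_345")    # 4
#' @export
dechlorinationEeq <- function(from, to) {
  nf <- .clCount(from); nt <- .clCount(to)
  if (any(nt > nf))
    stop("'to' is more chlorinated than 'from': dechlorination runs down the ladder")
  as.integer(2L * (nf - nt))
}

.MASS_UNITS <- c("ug_per_g", "mg_per_g")

#' Convert a soil mass concentration to per-bottle micromoles
#'
#' `value [ug or mg per g soil] * soilMass [g] / molarMass [g/mol]`, with the
#' unit prefix handled, giving umol per bottle.
#'
#' @param value measured concentration (>= 0).
#' @param unit `"ug_per_g"` or `"mg_per_g"`.
#' @param molarMass g/mol of the analyte.
#' @param geometry a [BottleGeometry-class]; supplies the soil mass.
#' @return umol of analyte per bottle.
#' @examples
#' massToMicromoles(0.40, "mg_per_g", molarMasses()[["SO4"]])  # 62.46
#' massToMicromoles(20, "ug_per_g", molarMasses()[["PCP"]])    # 1.126 (spike)
#' @export
massToMicromoles <- function(value, unit = c("ug_per_g", "mg_per_g"),
                             molarMass, geometry = bottleGeometry()) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(value), all(value >= 0 | is.na(value)),
            is.numeric(molarMass), molarMass > 0)
  validObject(geometry)
  ug <- switch(unit, ug_per_g = value, mg_per_g = value * 1000)
  ug * geometry@soilMass / molarMass
}

#' @describeIn massToMicromoles inverse conversion, umol per bottle back to a
#'   soil concentration in the requested unit.
#' @param umol per-bottle micromoles.
#' @export
micromolesToMass <- function(umol, unit = c("ug_per_g", "mg_per_g"),
                             molarMass, geometry = bottleGeometry()) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(umol), is.numeric(molarMass), molarMass > 0)
  validObject(geometry)
  ug <- umol * molarMass / geometry@soilMass
  switch(unit, ug_per_g = ug, mg_per_g = ug / 1000)
}

#' Convert a headspace per-mille reading to per-bottle micromoles
#'
#' The gas chromatograph reports headspace methane as a per-mille fraction;
#' the conversion to moles uses the calibrated `headspaceGasBasis` of the
#' bottle geometry (default 1000 umol, i.e. 1 permil == 1 umol).
#'
#' @param value permil reading in `[0, 1000]`.
#' @param geometry a [BottleGeometry-class].
#' @return umol of gas per bottle.
#' @examples
#' permilToMicromoles(169.1)      # 169.1 umol CH4 under the default basis
#' permilToMicromoles(169.1) * 8  # 1352.8 umol electron equivalents
#' @export
permilToMicromoles <- function(value, geometry = bottleGeometry()) {
  stopifnot(is.numeric(value))
  if (any(value < 0 | value > 1000, na.rm = TRUE))
    stop("permil readings must lie in [0, 1000]")
  validObject(geometry)
  value / 1000 * geometry@headspaceGasBasis
}
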