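# Synthetic endpoint generator for the 3-group x 3-amendment anaerobic
# incubation design: draws bottle chemistry by inverting the electron
# stoichiometry from a per-treatment electron allocation, plus measurement
# noise, and emits the hidden ground-truth ledger alongside.

#' Default incubation simulation preset
#'
#' Mean per-treatment electron allocations (umol e- per bottle), sterile
#' baselines and residual chlorophenol concentrations emulating a flooded
#' PCP-spiked soil incubation: the terminal-electron-acceptor ladder
#' Fe(III) >> sulfate > dechlorination with methanogenesis fed by the
#' remaining pool; AQDS (an electron shuttle) boosts iron reduction and
#' depresses sulfate reduction and dechlorination; biochar boosts both iron
#' and sulfate reduction; molybdate suppresses sulfate reduction to a small
#' residual and roughly halves the total electron budget.  Group mean totals
#' are ~3568 umol (biotic) and ~1759 umol (biotic + molybdate).
#'
#' @return `data.frame`, one row per (group, amendment) cell, with sterile
#'   baselines (`fe2_base_mg_g`, `so4_base_mg_g`), electron allocations
#'   (`e_fe`, `e_so4`, `e_ch4`, umol), product concentrations
#'   (`tecp_ug_g`, `tcp_ug_g`, `dcp_ug_g`), `pcp_ug_g` residual, `ph`,
#'   `eh_mv`, `co2_permil`, `doc_mg_kg`, `don_mg_kg`.
#' @export
incubationPreset <- function() {
  p <- expand.grid(amendment = .AMENDMENTS, group = .GROUPS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- p[, c("group", "amendment")]
  key <- paste(p$group, p$amendment, sep = ".")
  col <- function(...) {
    v <- c(...)
    unname(v[key])
  }
  # sterile baselines shared by the amendment-matched biotic cells
  feB <- c(control = 5.6, AQDS = 4.4, biochar = 5.0)
  soB <- c(control = 0.74, AQDS = 0.77, biochar = 0.74)
  p$fe2_base_mg_g <- feB[p$amendment]
  p$so4_base_mg_g <- soB[p$amendment]
  p$e_fe <- col(sterile_abiotic.control = 0, sterile_abiotic.AQDS = 0,
                sterile_abiotic.biochar = 0,
                biotic.control = 1217, biotic.AQDS = 2096,
                biotic.biochar = 1800,
                biotic_molybdate.control = 1100, biotic_molybdate.AQDS = 1400,
                biotic_molybdate.biochar = 1203)
  p$e_so4 <- col(sterile_abiotic.control = 0, sterile_abiotic.AQDS = 0,
                 sterile_abiotic.biochar = 0,
                 biotic.control = 165, biotic.AQDS = 125,
                 biotic.biochar = 501,
                 biotic_molybdate.control = 62, biotic_molybdate.AQDS = 62,
                 biotic_molybdate.biochar = 62)
  p$e_ch4 <- col(sterile_abiotic.control = 0, sterile_abiotic.AQDS = 0,
                 sterile_abiotic.biochar = 0,
                 biotic.control = 1600, biotic.AQDS = 1600,
                 biotic.biochar = 1600,
                 biotic_molybdate.control = 34.72, biotic_molybdate.AQDS = 0,
                 biotic_molybdate.biochar = 1352.8)
  p$tecp_ug_g <- col(sterile_abiotic.control = 0, sterile_abiotic.AQDS = 0,
                     sterile_abiotic.biochar = 0,
                     biotic.control = 10, biotic.AQDS = 4.5,
                     biotic.biochar = 10,
                     biotic_molybdate.control = 5, biotic_molybdate.AQDS = 1.2,
                     biotic_molybdate.biochar = 5)
  p$tcp_ug_g <- ifelse(p$group == "sterile_abiotic", 0, 0.5)
  p$dcp_ug_g <- 0
  p$pcp_ug_g <- col(sterile_abiotic.control = 15.8, sterile_abiotic.AQDS = 14.7,
                    sterile_abiotic.biochar = 13.9,
                    biotic.control = 6, biotic.AQDS = 10, biotic.biochar = 8,
                    biotic_molybdate.control = 11.6,
                    biotic_molybdate.AQDS = 14,
                    biotic_molybdate.biochar = 12.8)
  p$ph <- ifelse(p$group == "sterile_abiotic", 8.7, 8.5)
  p$eh_mv <- col(sterile_abiotic.control = -50, sterile_abiotic.AQDS = -50,
                 sterile_abiotic.biochar = -50,
                 biotic.control = -150, biotic.AQDS = -150,
                 biotic.biochar = -150,
                 biotic_molybdate.control = -140, biotic_molybdate.AQDS = -140,
                 biotic_molybdate.biochar = -140)
  p$co2_permil <- ifelse(p$group == "sterile_abiotic", 5,
                         ifelse(p$group == "biotic", 150, 100))
  p$nitrate_mg_g <- 0.02
  p$doc_mg_kg <- 150
  p$don_mg_kg <- 15
  p
}

# expectation-preserving lognormal noise
.lnNoise <- function(mu, cv, n = length(mu)) {
  if (cv <= 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  out <- mu
  pos <- mu > 0
  out[pos] <- rlnorm(sum(pos), meanlog = log(mu[pos]) - sdlog^2 / 2,
                     sdlog = sdlog)
  out
}

#' Simulate an anaerobic incubation endpoint table
#'
#' For every bottle of the 3 groups x 3 amendments x `nReplicates` design,
#' converts the preset's per-treatment electron allocation back into
#' observable endpoint chemistry via the bottle stoichiometry (the inverse
#' of [computeLedger()]), applies multiplicative lognormal measurement noise
#' to concentrations (additive Gaussian noise to Eh and pH, with spreads
#' proportional to `noiseCv`), and returns both the observable endpoints and
#' the hidden per-treatment true ledger.  Sterile bottles receive
#' sorption-only PCP losses, zero methane and baseline Fe(II)/sulfate.
#'
#' @param seed integer seed.
#' @param nReplicates bottles per treatment cell (default 3).
#' @param noiseCv relative measurement sd per analyte (default 0.05);
#'   0 gives a noiseless, exactly invertible table.
#' @param preset per-treatment design table, see [incubationPreset()].
#' @param geometry a [BottleGeometry-class].
#' @return list with `endpoints` (columns [endpointColumns()]) and `truth`
#'   (per-bottle true `e_fe`, `e_so4`, `e_dechlor`, `e_ch4`, `e_total`).
#' @examples
#' sim <- simulateIncubation(seed = 1, noiseCv = 0)
#' head(sim$endpoints)
#' @export
simulateIncubation <- function(seed = 1, nReplicates = 3, noiseCv = 0.05,
                               preset = incubationPreset(),
                               geometry = bottleGeometry()) {
  stopifnot(nReplicates >= 1, noiseCv >= 0)
  set.seed(seed)
  mw <- molarMasses()
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(preset))) {
    tr <- preset[i, ]
    eDechlor <- massToMicromoles(tr$tecp_ug_g, "ug_per_g", mw[["TeCP_2345"]],
                                 geometry) * 2 +
      massToMicromoles(tr$tcp_ug_g, "ug_per_g", mw[["TCP_345"]], geometry) * 4 +
      massToMicromoles(tr$dcp_ug_g, "ug_per_g", mw[["DCP_35"]], geometry) * 6
    # exact inversion of the stoichiometry at the treatment mean
    fe2 <- tr$fe2_base_mg_g +
      micromolesToMass(tr$e_fe / 1, "mg_per_g", mw[["Fe"]], geometry)
    so4 <- tr$so4_base_mg_g -
      micromolesToMass(tr$e_so4 / 8, "mg_per_g", mw[["SO4"]], geometry)
    ch4 <- tr$e_ch4 / 8 / geometry@headspaceGasBasis * 1000
    for (r in seq_len(nReplicates)) {
      conc <- .lnNoise(
        c(fe2 = fe2, so4 = so4, ch4 = ch4, pcp = tr$pcp_ug_g,
          tecp = tr$tecp_ug_g, tcp = tr$tcp_ug_g, dcp = tr$dcp_ug_g,
          no3 = tr$nitrate_mg_g, co2 = tr$co2_permil, doc = tr$doc_mg_kg,
          don = tr$don_mg_kg),
        noiseCv)
      rows[[length(rows) + 1L]] <- data.frame(
        group = tr$group, amendment = tr$amendment, replicate = r,
        fe2_mg_g = conc[["fe2"]], sulfate_mg_g = conc[["so4"]],
        nitrate_mg_g = conc[["no3"]], ch4_permil = conc[["ch4"]],
        co2_permil = conc[["co2"]], pcp_ug_g = conc[["pcp"]],
        tecp_ug_g = conc[["tecp"]], tcp_ug_g = conc[["tcp"]],
        dcp_ug_g = conc[["dcp"]],
        ph = tr$ph + rnorm(1, sd = 2 * noiseCv),
        eh_mv = tr$eh_mv + rnorm(1, sd = 200 * noiseCv),
        doc_mg_kg = conc[["doc"]], don_mg_kg = conc[["don"]],
        stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <- data.frame(
        group = tr$group, amendment = tr$amendment, replicate = r,
        e_fe = tr$e_fe, e_so4 = tr$e_so4, e_dechlor = eDechlor,
        e_ch4 = tr$e_ch4,
        e_total = tr$e_fe + tr$e_so4 + eDechlor + tr$e_ch4,
        stringsAsFactors = FALSE)
    }
  }
  endpoints <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  rownames(endpoints) <- rownames(truth) <- NULL
  list(endpoints = endpoints, truth = truth)
}
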