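# Per-bottle electron ledgers from endpoint chemistry, abiotic-baseline
# correction, and treatment-group summaries with compact letter displays.

#' Column layout of an endpoint table
#'
#' One row per bottle, measured at the end of the incubation.
#' @return character vector of the mandatory column names, in order.
#' @export
endpointColumns <- function() {
  c("group", "amendment", "replicate",
    "fe2_mg_g", "sulfate_mg_g", "nitrate_mg_g", "ch4_permil", "co2_permil",
    "pcp_ug_g", "tecp_ug_g", "tcp_ug_g", "dcp_ug_g",
    "ph", "eh_mv", "doc_mg_kg", "don_mg_kg")
}

.GROUPS <- c("sterile_abiotic", "biotic", "biotic_molybdate")
.AMENDMENTS <- c("control", "AQDS", "biochar")

#' Abiotic baseline for an analyte
#'
#' The sterile (gamma-irradiated) bottles carry all abiotic change --
#' background Fe(II), sorption, systematic loss -- so their mean is
#' subtracted from the biotic endpoints before electrons are counted.
#' With `matching = "matched"` (default) the mean is taken over sterile
#' bottles carrying the same amendment; if that cell is empty the pooled
#' sterile mean is used and a warning is raised.
#'
#' @param endpoints endpoint `data.frame` (see [endpointColumns()]).
#' @param analyte an endpoint column name, e.g. `"fe2_mg_g"`.
#' @param matching `"matched"` (amendment-matched) or `"pooled"`.
#' @param amendment amendment level for matched mode.
#' @return the baseline, in the analyte's own unit.
#' @export
abioticBaseline <- function(endpoints, analyte,
                            matching = c("matched", "pooled"),
                            amendment = NULL) {
  matching <- match.arg(matching)
  stopifnot(analyte %in% names(endpoints))
  sterile <- endpoints[endpoints$group == "sterile_abiotic", , drop = FALSE]
  if (nrow(sterile) == 0L)
    stop("no sterile_abiotic bottles: cannot form an abiotic baseline")
  if (matching == "matched") {
    if (is.null(amendment))
      stop("matched baseline needs an amendment")
    hit <- sterile[sterile$amendment == amendment, , drop = FALSE]
    if (nrow(hit) == 0L) {
      warning(sprintf(
        "no sterile bottles with amendment '%s'; falling back to pooled mean",
        amendment))
      hit <- sterile
    }
    return(mean(hit[[analyte]], na.rm = TRUE))
  }
  mean(sterile[[analyte]], na.rm = TRUE)
}

.ledgerFromDeltas <- function(dFe2, dSulfate, ch4, tecp, tcp, dcp, geometry) {
  mw <- molarMasses()
  clip <- function(x, what) {
    if (is.na(x)) return(NA_real_)
    if (x < 0) {
      warning(sprintf("negative baseline-corrected delta for %s clipped to 0",
                      what))
      return(0)
    }
    x
  }
  dFe2 <- clip(dFe2, "Fe(II)")
  dSulfate <- clip(dSulfate, "sulfate")
  eFe <- massToMicromoles(dFe2, "mg_per_g", mw[["Fe"]], geometry) *
    eeqPerMol("ferrous_iron")
  eSo4 <- massToMicromoles(dSulfate, "mg_per_g", mw[["SO4"]], geometry) *
    eeqPerMol("sulfide")
  eCh4 <- permilToMicromoles(ch4, geometry) * eeqPerMol("methane_acetoclastic")
  prods <- c(TeCP_2345 = tecp, TCP_345 = tcp, DCP_35 = dcp)
  prods[is.na(prods)] <- 0
  eDechlor <- sum(vapply(names(prods), function(sp) {
    massToMicromoles(prods[[sp]], "ug_per_g", mw[[sp]], geometry) *
      dechlorinationEeq("PCP", sp)
  }, numeric(1)))
  c(e_fe = eFe, e_so4 = eSo4, e_dechlor = eDechlor, e_ch4 = eCh4)
}

#' Electron ledger for one bottle
#'
#' Converts a bottle's baseline-corrected endpoint chemistry into electron
#' equivalents per terminal-electron-accepting process:
#' `e_fe = 1 x umol(Fe(II) gain)`, `e_so4 = 8 x umol(sulfate loss)`,
#' `e_ch4 = 8 x umol(CH4)`, and `e_dechlor` summed over the accumulated
#' dechlorination products weighted by `2 x (Cl removed)`.  Product
#' accumulation (not PCP disappearance) defines the dechlorination term, so
#' sorption losses never inflate the ledger.  Negative deltas are clipped to
#' zero with a warning.
#'
#' @param endpoint a single endpoint row (`data.frame` row or named list).
#' @param baselines named list with elements `fe2_mg_g` and `sulfate_mg_g`
#'   (units of the endpoint table), e.g. from [abioticBaseline()].
#' @param geometry a [BottleGeometry-class].
#' @return one-row `data.frame` with `e_fe`, `e_so4`, `e_dechlor`, `e_ch4`,
#'   `e_total` in umol electrons per bottle.
#' @examples
#' ep <- list(group = "biotic", amendment = "biochar", replicate = 1,
#'            fe2_mg_g = 5.0, sulfate_mg_g = 0.34, ch4_permil = 0,
#'            tecp_ug_g = 0, tcp_ug_g = 0, dcp_ug_g = 0)
#' computeLedger(ep, baselines = list(fe2_mg_g = 5.0, sulfate_mg_g = 0.74))
#' @export
computeLedger <- function(endpoint, baselines, geometry = bottleGeometry()) {
  g <- function(nm) if (is.null(endpoint[[nm]])) NA_real_ else endpoint[[nm]]
  if (is.null(baselines$fe2_mg_g) || is.null(baselines$sulfate_mg_g))
    stop("baselines must provide fe2_mg_g and sulfate_mg_g")
  e <- .ledgerFromDeltas(
    dFe2 = g("fe2_mg_g") - baselines$fe2_mg_g,
    dSulfate = baselines$sulfate_mg_g - g("sulfate_mg_g"),
    ch4 = if (is.na(g("ch4_permil"))) 0 else g("ch4_permil"),
    tecp = g("tecp_ug_g"), tcp = g("tcp_ug_g"), dcp = g("dcp_ug_g"),
    geometry = geometry)
  out <- data.frame(group = g("group"), amendment = g("amendment"),
                    replicate = g("replicate"),
                    as.list(e), stringsAsFactors = FALSE)
  out$e_total <- sum(e)
  out
}

#' Electron ledgers for a whole endpoint table
#'
#' Applies [computeLedger()] to every non-sterile bottle, deriving the
#' Fe(II) and sulfate baselines from the sterile group.
#'
#' @param endpoints endpoint `data.frame` containing sterile and biotic rows.
#' @param geometry a [BottleGeometry-class].
#' @param baseline baseline strategy, `"matched"` or `"pooled"`; see
#'   [abioticBaseline()].
#' @return a `data.frame`, one row per biotic bottle, umol electrons.
#' @export
computeLedgers <- function(endpoints, geometry = bottleGeometry(),
                           baseline = c("matched", "pooled")) {
  baseline <- match.arg(baseline)
  biotic <- endpoints[endpoints$group != "sterile_abiotic", , drop = FALSE]
  if (nrow(biotic) == 0L) stop("no biotic bottles in the endpoint table")
  rows <- lapply(seq_len(nrow(biotic)), function(i) {
    row <- biotic[i, , drop = FALSE]
    bl <- list(
      fe2_mg_g = abioticBaseline(endpoints, "fe2_mg_g", baseline,
                                 amendment = row$amendment),
      sulfate_mg_g = abioticBaseline(endpoints, "sulfate_mg_g", baseline,
                                     amendment = row$amendment))
    computeLedger(row, bl, geometry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# compact letter display by insert-and-absorb on the pairwise p matrix
.compactLetters <- function(pmat, means, alpha = 0.05) {
  g <- names(means)
  n <- length(g)
  if (n == 1L) return(setNames("a", g))
  ord <- order(-means)              # letters follow decreasing means
  g <- g[ord]
  cols <- list(rep(TRUE, n))        # membership columns over g
  sig <- which(pmat < alpha, arr.ind = TRUE)
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- match(rownames(pmat)[sig[r, 1]], g)
      j <- match(colnames(pmat)[sig[r, 2]], g)
      if (sig[r, 1] >= sig[r, 2]) next   # upper triangle once
      k <- 1
      while (k <= length(cols)) {
        cl <- cols[[k]]
        if (cl[i] && cl[j]) {
          a <- cl; a[i] <- FALSE
          b <- cl; b[j] <- FALSE
          cols[[k]] <- a
          cols[[length(cols) + 1L]] <- b
        }
        k <- k + 1
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
          keep[a] <- FALSE
        else if (a < b && keep[a] && keep[b] &&
                 identical(cols[[a]], cols[[b]]))
          keep[b] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  # order columns by their first member so 'a' labels the largest mean
  first <- vapply(cols, function(cl) which(cl)[1], numeric(1))
  cols <- cols[order(first)]
  lab <- rep("", n)
  for (k in seq_along(cols))
    lab[cols[[k]]] <- paste0(lab[cols[[k]]], letters[k])
  setNames(lab, g)[match(names(means), g)]
}

#' Treatment-group summary with ANOVA and compact letter display
#'
#' Within each treatment group, compares the amendments (control, AQDS,
#' biochar) by one-way ANOVA at the 5% level, with Tukey HSD pairwise
#' comparisons condensed into a compact letter display (groups sharing a
#' letter are not significantly different).
#'
#' @param data a `data.frame` such as an endpoint table or ledger table.
#' @param response name of the numeric column to summarise.
#' @param factor name of the factor compared within each stratum
#'   (default `"amendment"`).
#' @param within name of the stratifying column (default `"group"`).
#' @param alpha significance level for the letters.
#' @return a `data.frame` with one row per (stratum, level): `mean`, `sd`,
#'   `n`, the stratum-level ANOVA `F` and `p`, and `letter`.  `F`/`p` are
#'   `NA` when the response has no variance or a cell has n < 2.
#' @export
summarizeGroups <- function(data, response, factor = "amendment",
                            within = "group", alpha = 0.05) {
  stopifnot(response %in% names(data), factor %in% names(data),
            within %in% names(data))
  out <- lapply(split(data, data[[within]]), function(d) {
    f <- droplevels(as.factor(d[[factor]]))
    y <- d[[response]]
    cell <- data.frame(
      stratum = d[[within]][1],
      level = levels(f),
      mean = as.numeric(tapply(y, f, mean)),
      sd = as.numeric(tapply(y, f, sd)),
      n = as.integer(tapply(y, f, length)),
      stringsAsFactors = FALSE)
    Fv <- NA_real_; pv <- NA_real_
    lab <- rep("a", nlevels(f))
    if (nlevels(f) >= 2 && all(cell$n >= 2) && stats::var(y) > 0) {
      fit <- aov(y ~ f)
      tab <- summary(fit)[[1]]
      Fv <- tab[["F value"]][1]
      pv <- tab[["Pr(>F)"]][1]
      if (is.finite(Fv)) {
        tk <- TukeyHSD(fit)$f
        pmat <- matrix(1, nlevels(f), nlevels(f),
                       dimnames = list(levels(f), levels(f)))
        prs <- strsplit(rownames(tk), "-", fixed = TRUE)
        for (r in seq_along(prs)) {
          a <- prs[[r]][1]; b <- prs[[r]][2]
          pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
        }
        lab <- .compactLetters(pmat, setNames(cell$mean, cell$level), alpha)
      } else {
        Fv <- NA_real_; pv <- NA_real_
      }
    }
    cell$F <- Fv; cell$p <- pv; cell$letter <- unname(lab)
    cell
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "stratum"] <- within
  names(out)[names(out) == "level"] <- factor
  rownames(out) <- NULL
  out
}
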