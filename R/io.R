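# Readers, writers and the end-to-end report bundle.

#' Read an endpoint table
#'
#' CSV with one row per bottle and the exact mandatory header of
#' [endpointColumns()]; unknown extra columns are accepted with a warning.
#' Values are sanity-checked: concentrations must be non-negative and
#' per-mille readings must lie in `[0, 1000]`; offending rows are reported
#' by line number.
#'
#' @param path CSV path.
#' @return a typed `data.frame` of endpoints.
#' @export
readEndpoints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- endpointColumns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("endpoint schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown endpoint column(s): ",
            paste(extra, collapse = ", "))
  df <- df[, need]
  numeric_cols <- setdiff(need, c("group", "amendment", "replicate"))
  for (cl in numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
  conc <- setdiff(numeric_cols, c("ph", "eh_mv"))
  for (cl in conc) {
    bad <- which(df[[cl]] < 0)
    if (length(bad))
      stop(sprintf("negative %s in row(s) %s", cl,
                   paste(bad, collapse = ", ")))
  }
  for (cl in c("ch4_permil", "co2_permil")) {
    bad <- which(df[[cl]] > 1000)
    if (length(bad))
      stop(sprintf("%s above 1000 permil in row(s) %s", cl,
                   paste(bad, collapse = ", ")))
  }
  df
}

#' @describeIn readEndpoints write an endpoint table to CSV.
#' @param endpoints endpoint `data.frame`.
#' @export
writeEndpoints <- function(endpoints, path) {
  write.csv(endpoints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an OTU table in QIIME-legacy TSV layout
#'
#' First column `#OTU_ID`, remaining columns sample ids, optional final
#' `taxonomy` column of semicolon-ranked lineages.
#'
#' @param path TSV path.
#' @param tree optional `phylo` attached to the returned object.
#' @return an [OtuExperiment-class].
#' @export
readOtuTable <- function(path, tree = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "", stringsAsFactors = FALSE, quote = "")
  if (names(df)[1] != "#OTU_ID")
    stop("OTU table schema error: first column must be '#OTU_ID'")
  ids <- as.character(df[[1]])
  taxonomy <- NULL
  if ("taxonomy" %in% names(df)) {
    taxonomy <- .parseLineages(df$taxonomy)
    rownames(taxonomy) <- ids
    df$taxonomy <- NULL
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- ids
  storage.mode(counts) <- "integer"
  otuExperiment(counts, taxonomy = taxonomy, tree = tree)
}

#' @describeIn readOtuTable write an `OtuExperiment` (or count matrix) as TSV.
#' @param x an `OtuExperiment` or OTU x sample count matrix.
#' @param lineages optional character vector written as a `taxonomy` column.
#' @export
writeOtuTable <- function(x, path, lineages = NULL) {
  counts <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  df <- data.frame(`#OTU_ID` = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(lineages)) df$taxonomy <- lineages
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' End-to-end analysis report
#'
#' Runs the whole pipeline on an endpoint table and (optionally) an OTU
#' table with tree: per-bottle electron ledgers, treatment-group summaries
#' with ANOVA letters, alpha diversity, generalized UniFrac, NMDS,
#' PERMANOVA on the molybdate condition, and the taxa-environment
#' association screen.  Writes `ledgers.csv`, `group_summary.csv`,
#' `alpha.csv`, `gunifrac.tsv`, `nmds.csv`, `permanova.txt`,
#' `associations.csv` and `run_log.txt` into `outDir`.  All randomness
#' (NMDS restarts, PERMANOVA permutations) flows from `seed`, so reruns
#' with an identical configuration are byte-identical.
#'
#' @param endpoints endpoint `data.frame` or CSV path.
#' @param otu optional [OtuExperiment-class] or OTU TSV path.
#' @param tree optional `phylo` or newick path (needed if `otu` lacks one).
#' @param sampleData optional per-sample metadata (`data.frame` or TSV path,
#'   rows in OTU-table column order, with `group`/`amendment`/`replicate`
#'   columns); needed for PERMANOVA and the association screen when `otu`
#'   is read from a bare TSV.
#' @param outDir output directory (created if absent).
#' @param seed master seed.
#' @param alpha generalized UniFrac moderation parameter.
#' @param k NMDS axes.
#' @param permutations PERMANOVA permutations.
#' @param baseline abiotic baseline strategy, see [computeLedgers()].
#' @param dominance relative-abundance threshold for the association screen.
#' @param geometry a [BottleGeometry-class].
#' @return (invisibly) a list with every computed table/object.
#' @export
runReport <- function(endpoints, otu = NULL, tree = NULL, outDir = ".",
                      sampleData = NULL, seed = 1, alpha = 0.5, k = 4,
                      permutations = 999, baseline = "matched",
                      dominance = 0.01, geometry = bottleGeometry()) {
  if (is.character(endpoints)) endpoints <- readEndpoints(endpoints)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.character(otu)) otu <- readOtuTable(otu, tree = tree)
  if (is.character(sampleData))
    sampleData <- read.table(sampleData, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!is.null(otu) &&
      (!is.null(sampleData) || (is.null(otuTree(otu)) && !is.null(tree)))) {
    if (is.null(sampleData))
      sampleData <- as.data.frame(SummarizedExperiment::colData(otu))
    otu <- otuExperiment(otuCounts(otu), taxonomy = taxonomyTable(otu),
                         tree = if (is.null(otuTree(otu))) tree
                                else otuTree(otu),
                         sampleData = sampleData)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  out <- list()

  out$ledgers <- computeLedgers(endpoints, geometry, baseline)
  write.csv(out$ledgers, file.path(outDir, "ledgers.csv"), row.names = FALSE)

  summaries <- lapply(c("e_fe", "e_so4", "e_dechlor", "e_ch4", "e_total"),
                      function(v) {
                        s <- summarizeGroups(out$ledgers, v)
                        cbind(response = v, s)
                      })
  out$groupSummary <- do.call(rbind, summaries)
  write.csv(out$groupSummary, file.path(outDir, "group_summary.csv"),
            row.names = FALSE)

  if (!is.null(otu)) {
    if (is.null(otuTree(otu)))
      stop("UniFrac requested but no tree is available: supply `tree=` ",
           "(newick path or phylo object)")
    out$alpha <- alphaDiversity(otu)
    write.csv(out$alpha, file.path(outDir, "alpha.csv"), row.names = FALSE)

    out$gunifrac <- generalizedUniFrac(otu, alpha = alpha)
    write.table(out$gunifrac, file.path(outDir, "gunifrac.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)

    out$nmds <- nmdsOrdination(out$gunifrac, k = k, seed = seed)
    nm <- data.frame(sample_id = rownames(nmdsPoints(out$nmds)),
                     nmdsPoints(out$nmds), stress = nmdsStress(out$nmds),
                     row.names = NULL)
    write.csv(nm, file.path(outDir, "nmds.csv"), row.names = FALSE)

    cd <- as.data.frame(SummarizedExperiment::colData(otu))
    if ("group" %in% names(cd) && length(unique(cd$group)) >= 2) {
      out$permanova <- permanovaTest(out$gunifrac, cd$group,
                                     permutations = permutations, seed = seed)
      writeLines(utils::capture.output(show(out$permanova)),
                 file.path(outDir, "permanova.txt"))
    }

    # dominant-OTU association screen against the endpoint chemistry means
    rel <- sweep(otuCounts(otu), 2, colSums(otuCounts(otu)), "/")
    dom <- rel[rowMeans(rel) > dominance, , drop = FALSE]
    if (nrow(dom) && all(c("group", "amendment", "replicate") %in% names(cd))) {
      keyO <- paste(cd$group, cd$amendment, cd$replicate)
      keyE <- paste(endpoints$group, endpoints$amendment, endpoints$replicate)
      hit <- match(keyO, keyE)
      if (!any(is.na(hit))) {
        envCols <- c("pcp_ug_g", "fe2_mg_g", "sulfate_mg_g", "ch4_permil",
                     "co2_permil", "ph", "eh_mv", "doc_mg_kg", "don_mg_kg")
        env <- endpoints[hit, envCols]
        out$associations <- associateTaxa(t(dom), env)
        write.csv(out$associations, file.path(outDir, "associations.csv"),
                  row.names = FALSE)
      }
    }
  }

  writeLines(c(
    sprintf("redoxbudget %s", as.character(packageVersion("redoxbudget"))),
    sprintf("seed: %d", seed),
    sprintf("baseline: %s", baseline),
    sprintf("gunifrac alpha: %g | nmds axes: %d | permutations: %d",
            alpha, k, permutations),
    sprintf("geometry: %g g soil, gas basis %g umol",
            geometry@soilMass, geometry@headspaceGasBasis),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = "."))),
    file.path(outDir, "run_log.txt"))
  invisible(out)
}
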