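## End-to-end orchestration on synthetic data, and the report bundle writer.

## genes called under a different fold-change/alpha rule without re-testing
.applyCallRule <- function(de, config) {
  p <- if (config@useAdjusted) de$pAdj else de$pRaw
  up <- p <= config@alpha & de$fc >= config@minFoldChange
  down <- p <= config@alpha & de$fc <= 1 / config@minFoldChange
  de$gene[up | down]
}

#' Run the whole subset-comparison pipeline on synthetic data
#'
#' Generates counts, network and annotations from the configuration, then:
#' size factors and the blind dispersion fit across all four samples; the
#' exact NB test per subset; length-bias weights and side-by-side ORA;
#' network cleaning (removing the promiscuous synthetic ubiquitin),
#' first-order expansion of the core molecules, and the modulator Venn
#' partition; per subset, a first-order network of that subset's DE genes,
#' score calibration, annealing search and module merging; hub
#' classification of the top merged module; and the concordance between the
#' filtered-modulator and unbiased analyses.
#'
#' Two DE calling rules are used: \code{deCallConfig} (raw p-value only,
#' the rule for DE lists, Venn comparison and ORA) and
#' \code{networkCallConfig} (BH-adjusted p plus a two-fold change, the
#' FDR-controlled rule for all network input, matching the planted
#' two-fold-or-more effects).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param deCallConfig,networkCallConfig \linkS4class{DEConfig}s, see above.
#' @param annealConfig an \linkS4class{AnnealingConfig}; its seed is
#'   re-derived from \code{seed} when that is given.
#' @param oraMinObserved minimum observed genes per ORA term.
#' @param exclusions symbols removed during network cleaning.
#' @param seed optional master seed overriding the configuration seeds.
#' @return a list with every intermediate and final result (see Details in
#'   the vignette); class \code{"pathmodPipeline"}.
#' @export
runPipeline <- function(cfg = simulationConfig(),
                        deCallConfig = deConfig(alpha = 0.05),
                        networkCallConfig = deConfig(alpha = 0.05,
                                                     useAdjusted = TRUE,
                                                     minFoldChange = 2),
                        annealConfig = annealingConfig(),
                        oraMinObserved = 10L,
                        exclusions = c("Ubc", "UBC_SYN"),
                        seed = NULL) {
  if (!is.null(seed)) {
    cfg@seed <- as.integer(seed)
    annealConfig@seed <- as.integer(seed) + 101L
  }
  sim <- genCounts(cfg)
  truth <- sim$truth
  net0 <- genNetwork(cfg, truth)
  ann <- genAnnotations(cfg, truth)
  se <- sim$se

  factors <- medianRatioSizeFactors(se)
  fit <- fitBlindDispersion(se, factors)
  deA <- callDE(se, "A", deCallConfig, factors, fit)
  deB <- callDE(se, "B", deCallConfig, factors, fit)
  cpm <- countsPerMillion(se, factors)

  universe <- rownames(se)
  lens <- SummarizedExperiment::rowData(se)$length
  mkWeights <- function(de) {
    flags <- universe %in% deGenes(de)
    if (sum(flags) < 2L || sum(!flags) < 2L) return(NULL)
    w <- fitLengthWeights(flags, lens)
    stats::setNames(w$weights, universe)
  }
  weights <- list(mkWeights(deA), mkWeights(deB))
  ora <- runORA(list(A = deGenes(deA), B = deGenes(deB)), ann, universe,
                weights = weights, minObserved = oraMinObserved)

  net <- cleanNetwork(net0, exclusions)
  cores <- truth$gene[truth$coreFlag]
  expanded <- firstOrderNeighborhood(net, cores)
  deNetA <- .applyCallRule(deA, networkCallConfig)
  deNetB <- .applyCallRule(deB, networkCallConfig)
  partition <- findModulators(expanded, deNetA, deNetB, cores)
  vennDE <- vennPartition(deGenes(deA), deGenes(deB))

  subnetFor <- function(de, deNet, offset) {
    deIn <- intersect(toupper(deNet), igraph::V(net@graph)$name)
    if (!length(deIn)) return(NULL)
    subNet <- firstOrderNeighborhood(net, deIn)
    scores <- scoreNodes(de, subNet)
    calib <- calibrateBackground(scores, seed = annealConfig@seed + offset)
    ac <- annealConfig
    ac@seed <- annealConfig@seed + offset
    mods <- annealSearch(subNet, scores, calib, ac)
    merged <- mergeModules(mods, scores, calib, subNet,
                           ac@mergeJaccard)
    list(network = subNet, scores = scores, calib = calib,
         modules = mods, merged = merged)
  }
  subA <- subnetFor(deA, deNetA, 1L)
  subB <- subnetFor(deB, deNetB, 2L)

  hubsFor <- function(sub, de) {
    if (is.null(sub) || !length(sub$merged)) return(NULL)
    classifyHubs(sub$merged[[1]], sub$network, de = de, cores = cores)
  }
  hubsA <- hubsFor(subA, deA)
  hubsB <- hubsFor(subB, deB)
  conc <- analysisConcordance(partition,
    list(A = if (is.null(subA)) list() else subA$merged,
         B = if (is.null(subB)) list() else subB$merged))

  structure(list(
    config = cfg, se = se, truth = truth, network = net0, annotations = ann,
    factors = factors, fit = fit, deA = deA, deB = deB, cpm = cpm,
    weights = weights, ora = ora, cleaned = net, expanded = expanded,
    deNetA = deNetA, deNetB = deNetB, partition = partition,
    vennDE = vennDE, subA = subA, subB = subB,
    hubsA = hubsA, hubsB = hubsB, concordance = conc,
    seeds = c(data = cfg@seed, search = annealConfig@seed)),
    class = "pathmodPipeline")
}

#' Write a report bundle for a pipeline run
#'
#' One directory with: \code{summary.json} (DE counts, Venn classes with
#' exact and display-rounded percentages, modulator partition, concordance,
#' module summaries, configuration echo and seeds), \code{venn.json} (the
#' three classes of each comparison), per-subset DE tables and the ORA
#' table as TSV, GraphML exports of the cleaned network and of each merged
#' module, and a plain-text run log.  Output is byte-identical across
#' reruns with the same seeds (no timestamps in the JSON).
#'
#' @param results a \code{"pathmodPipeline"} list from [runPipeline()].
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
writeReportBundle <- function(results, dir) {
  need <- c("deA", "deB", "ora", "partition", "vennDE", "concordance",
            "cleaned")
  missing <- need[!need %in% names(results) |
                  vapply(need, function(n) is.null(results[[n]]), TRUE)]
  if (length(missing))
    stop("missing upstream output(s): ", paste(missing, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vennList <- function(p)
    list(onlyA = length(p@onlyA), shared = length(p@shared),
         onlyB = length(p@onlyB),
         pctA = p@pctA, pctB = p@pctB,
         pctA_display = round(p@pctA), pctB_display = round(p@pctB))
  modSummary <- function(sub) {
    if (is.null(sub)) return(list())
    lapply(sub$merged, function(m)
      list(k = length(members(m)), zA = m@zA, score = m@score,
           members = members(m)))
  }
  summary <- list(
    nGenes = nrow(results$se),
    de = list(A = list(n = length(deGenes(results$deA)),
                       up = length(deGenes(results$deA, "up")),
                       down = length(deGenes(results$deA, "down"))),
              B = list(n = length(deGenes(results$deB)),
                       up = length(deGenes(results$deB, "up")),
                       down = length(deGenes(results$deB, "down")))),
    vennDE = vennList(results$vennDE),
    modulators = vennList(results$partition),
    concordance = results$concordance,
    modules = list(A = modSummary(results$subA),
                   B = modSummary(results$subB)),
    oraRetainedTerms = nrow(results$ora),
    seeds = as.list(results$seeds))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(de = vennList(results$vennDE),
         modulators = vennList(results$partition)),
    file.path(dir, "venn.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeTSV <- function(x, f)
    utils::write.table(as.data.frame(x), file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeTSV(results$deA, "de_A.tsv")
  writeTSV(results$deB, "de_B.tsv")
  writeTSV(results$ora, "ora.tsv")
  writeGraphML(results$cleaned, file.path(dir, "network_cleaned.graphml"))
  writeMods <- function(sub, tag) {
    if (is.null(sub)) return()
    for (i in seq_along(sub$merged))
      writeGraphML(sub$network,
                   file.path(dir, sprintf("module_%s_%d.graphml", tag, i)),
                   nodes = members(sub$merged[[i]]))
  }
  writeMods(results$subA, "A")
  writeMods(results$subB, "B")
  log <- c(sprintf("pathmod %s", as.character(utils::packageVersion("pathmod"))),
           sprintf("R %s", R.version.string),
           sprintf("data seed: %d", results$seeds[["data"]]),
           sprintf("search seed: %d", results$seeds[["search"]]),
           utils::capture.output(show(results$config)))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
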