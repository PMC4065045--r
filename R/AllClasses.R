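#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configuration of the synthetic two-subset stimulation experiment
#'
#' Holds every knob of the synthetic-data generators: the size of the gene
#' universe, the number of designated core signalling molecules, the planted
#' differential-expression structure, the negative binomial noise model
#' (variance = mu + phi * mu^2), the length-dependent detection bias, the
#' interaction-network growth parameters and the annotation-term layout.
#'
#' @slot nGenes number of genes in the universe.
#' @slot nCore number of designated core signalling molecules, wired as
#'   high-degree nodes of the synthetic interactome.
#' @slot nModulatorsPerSubset number of planted subset-specific pathway
#'   modulators attached to core nodes; must not exceed the number of
#'   subset-specific DE genes, \code{floor(fracSubsetDE * nGenes)}.
#' @slot baselineMean median of the log-normal distribution of per-gene
#'   baseline negative binomial means.
#' @slot dispersion negative binomial dispersion phi (variance
#'   \eqn{\mu + \phi\mu^2}); 0 gives Poisson counts.
#' @slot foldChange multiplicative effect applied to planted DE genes in the
#'   stimulated sample of the affected subset(s); must be >= 1, and 1 means
#'   no structure is planted at all.
#' @slot fracSharedDE,fracSubsetDE fractions of the universe planted as DE in
#'   both subsets, respectively in exactly one subset (per subset).  Planted
#'   counts use \code{floor()} when the products are non-integral.
#' @slot lengthBiasStrength slope of the planted DE probability against
#'   standardised log gene length (0 = no length bias).
#' @slot netAttachM edges added per new node during preferential attachment.
#' @slot termSizes integer vector of annotation-term sizes.
#' @slot termOdds per-term planted enrichment odds, recycled along
#'   \code{termSizes}; odds 1 marks an unenriched term.
#' @slot seed integer RNG seed; every generator is deterministic given it.
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    nCore = "integer",
    nModulatorsPerSubset = "integer",
    baselineMean = "numeric",
    dispersion = "numeric",
    foldChange = "numeric",
    fracSharedDE = "numeric",
    fracSubsetDE = "numeric",
    lengthBiasStrength = "numeric",
    netAttachM = "integer",
    termSizes = "integer",
    termOdds = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L || object@nCore < 1L || object@netAttachM < 1L)
    msg <- c(msg, "all counts must be >= 1")
  if (object@nCore >= object@nGenes)
    msg <- c(msg, "nCore must be smaller than nGenes")
  if (object@foldChange < 1)
    msg <- c(msg, "foldChange must be >= 1")
  if (object@baselineMean <= 0 || object@dispersion < 0)
    msg <- c(msg, "baselineMean must be > 0 and dispersion >= 0")
  if (object@fracSharedDE < 0 || object@fracSubsetDE < 0 ||
      object@fracSharedDE + 2 * object@fracSubsetDE > 1)
    msg <- c(msg, "need fracSharedDE + 2*fracSubsetDE <= 1 with both >= 0")
  if (object@lengthBiasStrength < 0)
    msg <- c(msg, "lengthBiasStrength must be >= 0")
  if (object@foldChange > 1 &&
      object@nModulatorsPerSubset >
        floor(object@fracSubsetDE * object@nGenes))
    msg <- c(msg, paste0("nModulatorsPerSubset exceeds the number of ",
                         "subset-specific DE genes floor(fracSubsetDE*nGenes)"))
  if (any(object@termSizes < 1L))
    msg <- c(msg, "termSizes must all be >= 1")
  if (any(object@termOdds <= 0))
    msg <- c(msg, "termOdds must all be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 5,000-gene universe with 48 core signalling molecules, 2% shared and 1%
#' per-subset planted DE genes at fold change 4, a moderate length bias, and
#' sample depths proportional to the mapped library sizes of a
#' single-replicate two-subset stimulation experiment.  The default
#' dispersion of 0.02 reflects single libraries prepared from RNA pooled
#' over many animals, where biological variation is averaged out and
#' residual overdispersion is modest.
#'
#' @param nGenes,nCore,nModulatorsPerSubset,baselineMean,dispersion,foldChange
#'   see \linkS4class{SimulationConfig}.
#' @param fracSharedDE,fracSubsetDE,lengthBiasStrength,netAttachM see
#'   \linkS4class{SimulationConfig}.
#' @param termSizes,termOdds annotation-term sizes and planted odds (recycled);
#'   the default includes an 8-member term so the downstream minimum-size
#'   filter is exercised.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 500, nCore = 10, nModulatorsPerSubset = 5)
#' @export
simulationConfig <- function(nGenes = 5000L, nCore = 48L,
                             nModulatorsPerSubset = 40L,
                             baselineMean = 200, dispersion = 0.02,
                             foldChange = 4,
                             fracSharedDE = 0.02, fracSubsetDE = 0.01,
                             lengthBiasStrength = 0.5,
                             netAttachM = 2L,
                             termSizes = c(8L, 15L, 20L, 30L, 50L, 50L,
                                           50L, 75L, 100L, 150L),
                             termOdds = c(1, 6),
                             seed = 20140620L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nCore = as.integer(nCore),
      nModulatorsPerSubset = as.integer(nModulatorsPerSubset),
      baselineMean = baselineMean, dispersion = dispersion,
      foldChange = foldChange,
      fracSharedDE = fracSharedDE, fracSubsetDE = fracSubsetDE,
      lengthBiasStrength = lengthBiasStrength,
      netAttachM = as.integer(netAttachM),
      termSizes = as.integer(termSizes),
      termOdds = rep_len(as.numeric(termOdds), length(termSizes)),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      object@nCore, "cores,",
      object@nModulatorsPerSubset, "modulators/subset\n")
  cat("  NB mean ~ logN(log ", object@baselineMean, "), phi = ",
      object@dispersion, ", fold change = ", object@foldChange, "\n", sep = "")
  cat("  planted DE: ", object@fracSharedDE, " shared + ",
      object@fracSubsetDE, " per subset; length bias ",
      object@lengthBiasStrength, "\n", sep = "")
  cat("  network m =", object@netAttachM, "; ",
      length(object@termSizes), "annotation terms; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## Chimeric gene model
## ---------------------------------------------------------------------------

#' Per-gene chimeric exon model
#'
#' The union of all protein-coding transcripts' exons of each gene, stored as
#' a \code{GRangesList} of disjoint sorted intervals (0-based half-open
#' internally converted to the 1-based closed \code{IRanges} convention at the
#' reader boundary).
#'
#' @slot exons a \code{GRangesList}, one element per gene, disjoint and sorted.
#' @export
setClass("ChimericGeneModel", representation(exons = "CompressedGRangesList"))

setMethod("show", "ChimericGeneModel", function(object) {
  n <- length(object@exons)
  cat("ChimericGeneModel with", n, "genes;",
      sum(lengths(object@exons)), "merged exons; total exonic length",
      sum(exonicLength(object)), "\n")
})

## ---------------------------------------------------------------------------
## Dispersion fit
## ---------------------------------------------------------------------------

#' Pooled ("blind") mean-variance fit
#'
#' Stores the smooth variance function fitted by treating every sample as a
#' replicate of every other, plus the per-gene pooled means and variances it
#' was fitted to.  Only the fitted trend is used downstream ("fit-only"):
#' per-gene empirical variances never override it.
#'
#' @slot method "parametric" (gamma-family IRLS of variance on mu and mu^2) or
#'   "local" (loess of log excess variance on log mean).
#' @slot xi mean of 1/sizeFactor, the shot-noise scale on the common scale.
#' @slot coefs numeric; for the parametric fit, c(b0, b1) of
#'   v(mu) = b0*mu + b1*mu^2.
#' @slot localFit the loess object for method = "local" (otherwise NULL).
#' @slot baseMean,baseVar per-gene pooled normalised means and variances.
#' @export
setClass("DispersionFit",
  representation(method = "character", xi = "numeric", coefs = "numeric",
                 localFit = "ANY", baseMean = "numeric", baseVar = "numeric"))

setMethod("show", "DispersionFit", function(object) {
  cat("DispersionFit (", object@method, ", fit-only) on ",
      length(object@baseMean), " genes\n", sep = "")
  if (object@method == "parametric")
    cat("  v(mu) = ", signif(object@coefs[1], 4), "*mu + ",
        signif(object@coefs[2], 4), "*mu^2  (clamped at mu)\n", sep = "")
})

## ---------------------------------------------------------------------------
## DE results
## ---------------------------------------------------------------------------

#' Per-gene differential expression results
#'
#' A \code{DataFrame} with columns gene, meanA, meanB (normalised), fc,
#' log2fc, pRaw, pAdj (Benjamini-Hochberg) and call (up/down/ns), with the
#' \code{DEConfig} used stored in \code{metadata()}.
#' @export
setClass("DEResult", contains = "DFrame")

#' Differential expression calling configuration
#'
#' @slot alpha significance threshold (inclusive: p <= alpha is called).
#' @slot useAdjusted call on BH-adjusted p-values (meta-analysis path) rather
#'   than raw p-values (single-replicate RNA-Seq path).
#' @slot minFoldChange minimum fold change; up needs fc >= minFoldChange,
#'   down needs fc <= 1/minFoldChange.
#' @export
setClass("DEConfig",
  representation(alpha = "numeric", useAdjusted = "logical",
                 minFoldChange = "numeric"))

setValidity("DEConfig", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@minFoldChange < 1) return("minFoldChange must be >= 1")
  TRUE
})

#' @rdname DEConfig-class
#' @param alpha,useAdjusted,minFoldChange see slots.
#' @return a \linkS4class{DEConfig}.
#' @export
deConfig <- function(alpha = 0.05, useAdjusted = FALSE, minFoldChange = 1) {
  new("DEConfig", alpha = alpha, useAdjusted = useAdjusted,
      minFoldChange = minFoldChange)
}

## ---------------------------------------------------------------------------
## Interaction network
## ---------------------------------------------------------------------------

#' Undirected simple interaction network
#'
#' Wraps an \pkg{igraph} graph of gene symbols.  Matching is
#' case-insensitive: vertices are keyed by upper-cased symbol and keep a
#' case-preserving display form in the vertex attribute \code{display}.
#'
#' @slot graph an undirected simple \pkg{igraph} graph.
#' @export
setClass("InteractionNetwork", representation(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    return("graph must be simple (no self-loops, no parallel edges)")
  TRUE
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat("InteractionNetwork:", igraph::vcount(g), "nodes,",
      igraph::ecount(g), "edges\n")
})

## ---------------------------------------------------------------------------
## Active subnetworks
## ---------------------------------------------------------------------------

#' A scored subnetwork
#'
#' @slot members node symbols of the subnetwork.
#' @slot zA raw aggregate score, sum(z)/sqrt(k).
#' @slot score calibrated score (zA - mu_k)/sigma_k.
#' @slot connected whether the members induce a connected subgraph.
#' @export
setClass("Subnetwork",
  representation(members = "character", zA = "numeric", score = "numeric",
                 connected = "logical"))

setMethod("show", "Subnetwork", function(object) {
  cat("Subnetwork: k =", length(object@members),
      "| zA =", round(object@zA, 3),
      "| s =", round(object@score, 3),
      if (object@connected) "(connected)\n" else "(NOT connected)\n")
})

#' Monte-Carlo background calibration of subnetwork scores
#'
#' For each subset size k, the mean and standard deviation of the raw score
#' sum(z)/sqrt(k) over random node sets (connectivity not required).
#' Scores at sizes between calibrated ones are interpolated linearly.
#'
#' @slot sizes calibrated sizes.
#' @slot mu,sigma background mean and sd per size.
#' @slot nDraws Monte-Carlo draws per size.
#' @slot seed RNG seed used.
#' @export
setClass("CalibrationTable",
  representation(sizes = "integer", mu = "numeric", sigma = "numeric",
                 nDraws = "integer", seed = "integer"))

setMethod("show", "CalibrationTable", function(object) {
  cat("CalibrationTable over", length(object@sizes), "sizes (",
      min(object@sizes), "..", max(object@sizes), "),",
      object@nDraws, "draws each\n")
})

#' Simulated annealing configuration
#'
#' @slot iterations single-node toggle proposals per restart.
#' @slot tStart,tEnd geometric temperature schedule endpoints.
#' @slot nModules number of top modules to report.
#' @slot restarts independent restarts; best final state wins.
#' @slot seed RNG seed.
#' @slot mergeJaccard node-set Jaccard threshold for merging modules.
#' @export
setClass("AnnealingConfig",
  representation(iterations = "integer", tStart = "numeric", tEnd = "numeric",
                 nModules = "integer", restarts = "integer", seed = "integer",
                 mergeJaccard = "numeric"))

setValidity("AnnealingConfig", function(object) {
  if (!(object@tStart > object@tEnd && object@tEnd > 0))
    return("need tStart > tEnd > 0")
  if (object@iterations < 1L) return("iterations must be >= 1")
  TRUE
})

#' @rdname AnnealingConfig-class
#' @param iterations,tStart,tEnd,nModules,restarts,seed,mergeJaccard see slots.
#' @return an \linkS4class{AnnealingConfig}.
#' @export
annealingConfig <- function(iterations = 50000L, tStart = 1.0, tEnd = 0.01,
                            nModules = 5L, restarts = 3L, seed = 20140620L,
                            mergeJaccard = 0.5) {
  new("AnnealingConfig", iterations = as.integer(iterations), tStart = tStart,
      tEnd = tEnd, nModules = as.integer(nModules),
      restarts = as.integer(restarts), seed = as.integer(seed),
      mergeJaccard = mergeJaccard)
}

## ---------------------------------------------------------------------------
## Modulator partition
## ---------------------------------------------------------------------------

#' Venn partition of two subsets' modulator (or DE) sets
#'
#' @slot setA,setB the two input sets.
#' @slot onlyA,shared,onlyB the three disjoint Venn classes.
#' @slot pctA,pctB exact subset-specific percentages,
#'   100*|A only|/|A| and 100*|B only|/|B|.
#' @export
setClass("ModulatorPartition",
  representation(setA = "character", setB = "character",
                 onlyA = "character", shared = "character",
                 onlyB = "character", pctA = "numeric", pctB = "numeric"))

setMethod("show", "ModulatorPartition", function(object) {
  cat("ModulatorPartition: |A| =", length(object@setA),
      "|B| =", length(object@setB), "\n")
  cat("  A-only", length(object@onlyA),
      "(", round(object@pctA), "% of A ) | shared", length(object@shared),
      "| B-only", length(object@onlyB),
      "(", round(object@pctB), "% of B )\n")
})

## ---------------------------------------------------------------------------
## Hub configuration
## ---------------------------------------------------------------------------

#' Hub classification thresholds
#'
#' Hubs are nodes with \code{hubMinDegree} (default 5) or more interactions;
#' the most highly interconnected hubs have \code{superHubMinDegree}
#' (default 15) or more.  Both thresholds are inclusive.
#' @slot hubMinDegree,superHubMinDegree inclusive degree thresholds.
#' @export
setClass("HubConfig",
  representation(hubMinDegree = "integer", superHubMinDegree = "integer"))

setValidity("HubConfig", function(object) {
  if (!(object@superHubMinDegree >= object@hubMinDegree &&
        object@hubMinDegree >= 1L))
    return("need superHubMinDegree >= hubMinDegree >= 1")
  TRUE
})

#' @rdname HubConfig-class
#' @param hubMinDegree,superHubMinDegree inclusive degree thresholds.
#' @return a \linkS4class{HubConfig}.
#' @export
hubConfig <- function(hubMinDegree = 5L, superHubMinDegree = 15L) {
  new("HubConfig", hubMinDegree = as.integer(hubMinDegree),
      superHubMinDegree = as.integer(superHubMinDegree))
}
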