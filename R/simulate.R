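## Synthetic-data generators: counts with planted DE structure, a scale-free
## interaction network with designated core molecules and planted modulators,
## annotation sets with planted enrichment, and exon models plus alignment
## intervals for the counting stage.  Every generator is deterministic given
## the configuration seed.

.SAMPLE_NAMES <- c("A_steady", "A_stimulated", "B_steady", "B_stimulated")
## relative sequencing depths of the four samples, proportional to the mapped
## library sizes of a single-replicate two-subset stimulation experiment
.DEPTH_FACTORS <- c(1.000, 0.826, 0.950, 0.385)

#' Generate a synthetic two-subset stimulation count matrix with ground truth
#'
#' Four samples (two subsets x steady/stimulated) of negative binomial counts
#' sharing per-gene baseline means.  Planted DE genes carry the configured
#' fold change multiplicatively in the stimulated sample of the affected
#' subset(s); 85% of planted effects are up-regulations.  Gene lengths are
#' log-normal and, when \code{lengthBiasStrength > 0}, longer genes are more
#' likely to be chosen as planted DE genes (the detection bias the enrichment
#' weighting must correct).  Core molecules are never planted DE; planted
#' modulators are drawn from the subset-specific DE genes of each subset.
#' With \code{foldChange = 1} no structure is planted and all truth flags are
#' off.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a list with elements \code{se} (a \code{SummarizedExperiment};
#'   assay \code{counts}, \code{rowData} \code{length},
#'   \code{colData} \code{subset}/\code{condition}) and \code{truth}
#'   (a \code{DataFrame} with per-gene \code{deStatusA}, \code{deStatusB}
#'   in \{none, up, down\}, \code{modulatorOf} in \{NA, "A", "B"\} and
#'   \code{coreFlag}).
#' @examples
#' sim <- genCounts(simulationConfig(nGenes = 300, nCore = 8,
#'                                   nModulatorsPerSubset = 3))
#' table(sim$truth$deStatusA)
#' @export
genCounts <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nGenes
  genes <- c(sprintf("CORE%03d", seq_len(cfg@nCore)),
             sprintf("G%06d", seq_len(n - cfg@nCore)))
  core <- c(rep(TRUE, cfg@nCore), rep(FALSE, n - cfg@nCore))
  len <- pmax(150L, as.integer(round(stats::rlnorm(n, log(2000), 0.7))))
  mu <- stats::rlnorm(n, log(cfg@baselineMean), 1.2)

  deA <- deB <- rep("none", n)
  modOf <- rep(NA_character_, n)
  if (cfg@foldChange > 1) {
    nShared <- floor(cfg@fracSharedDE * n)
    nSub <- floor(cfg@fracSubsetDE * n)
    zlen <- as.numeric(scale(log(len)))
    w <- exp(cfg@lengthBiasStrength * zlen)
    cand <- which(!core)
    pick <- function(pool, k) {
      if (k == 0L) return(integer())
      pool[sample.int(length(pool), k, prob = w[pool])]
    }
    shared <- pick(cand, nShared)
    cand <- setdiff(cand, shared)
    subA <- pick(cand, nSub)
    cand <- setdiff(cand, subA)
    subB <- pick(cand, nSub)
    dirOf <- function(idx)
      ifelse(stats::runif(length(idx)) < 0.85, "up", "down")
    dShared <- dirOf(shared); dA <- dirOf(subA); dB <- dirOf(subB)
    deA[shared] <- dShared; deB[shared] <- dShared
    deA[subA] <- dA
    deB[subB] <- dB
    if (cfg@nModulatorsPerSubset > 0L) {
      modOf[sample(subA, cfg@nModulatorsPerSubset)] <- "A"
      modOf[sample(subB, cfg@nModulatorsPerSubset)] <- "B"
    }
  }

  fc <- matrix(1, n, 4L, dimnames = list(genes, .SAMPLE_NAMES))
  eff <- function(status) ifelse(status == "up", cfg@foldChange,
                          ifelse(status == "down", 1 / cfg@foldChange, 1))
  fc[, "A_stimulated"] <- eff(deA)
  fc[, "B_stimulated"] <- eff(deB)

  counts <- matrix(0L, n, 4L, dimnames = list(genes, .SAMPLE_NAMES))
  for (j in 1:4) {
    m <- mu * .DEPTH_FACTORS[j] * fc[, j]
    counts[, j] <- if (cfg@dispersion > 0)
      stats::rnbinom(n, mu = m, size = 1 / cfg@dispersion)
    else stats::rpois(n, m)
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = len, row.names = genes),
    colData = S4Vectors::DataFrame(
      subset = c("A", "A", "B", "B"),
      condition = c("steady", "stimulated", "steady", "stimulated"),
      row.names = .SAMPLE_NAMES))
  truth <- S4Vectors::DataFrame(
    gene = genes, length = len, baselineMean = mu,
    deStatusA = deA, deStatusB = deB, modulatorOf = modOf, coreFlag = core,
    row.names = genes)
  S4Vectors::metadata(truth)$config <- cfg
  list(se = se, truth = truth)
}

## sample m distinct preferential-attachment targets from the endpoint bag,
## optionally excluding a node set; falls back to uniform sampling over the
## eligible existing nodes when the bag keeps returning excluded/duplicate ones
.paTargets <- function(bag, m, exclude, existing) {
  out <- integer()
  tries <- 0L
  while (length(out) < m && tries < 50L * m) {
    cand <- bag[sample.int(length(bag), 1L)]
    tries <- tries + 1L
    if (!(cand %in% out) && !(cand %in% exclude)) out <- c(out, cand)
  }
  if (length(out) < m) {
    pool <- setdiff(setdiff(existing, exclude), out)
    out <- c(out, pool[sample.int(length(pool),
                                  min(m - length(out), length(pool)))])
  }
  out
}

#' Generate a scale-free interaction network matching a ground truth
#'
#' Preferential attachment seeded from a clique over the core molecules, so
#' cores end up as high-degree hubs (degree at least the 90th percentile,
#' enforced).  Every planted modulator receives at least one edge to a core
#' node, while planted DE genes that are \emph{not} designated modulators are
#' kept out of core neighbourhoods, so the filtered first-order analysis has
#' exact planted answers.  One synthetic promiscuous node \code{UBC_SYN}
#' with degree >= 0.3 * nGenes is included for cleaning tests.
#'
#' @param cfg the \linkS4class{SimulationConfig} used for the counts.
#' @param truth the ground-truth \code{DataFrame} from [genCounts()].
#' @return an \linkS4class{InteractionNetwork} over all genes plus
#'   \code{UBC_SYN}.
#' @export
genNetwork <- function(cfg, truth) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (nrow(truth) != cfg@nGenes || sum(truth$coreFlag) != cfg@nCore)
    stop("gene universe of `truth` does not match `cfg`")
  set.seed(cfg@seed + 1L)
  n <- cfg@nGenes
  m <- cfg@netAttachM
  genes <- truth$gene
  coreIdx <- which(truth$coreFlag)
  isModulator <- !is.na(truth$modulatorOf)
  ## planted DE genes that are not designated modulators must not touch cores
  avoidCores <- (truth$deStatusA != "none" | truth$deStatusB != "none") &
    !isModulator

  edges <- vector("list", n + 2L)
  ne <- 0L
  addEdges <- function(a, b) {
    ne <<- ne + 1L
    edges[[ne]] <<- cbind(a, b)
  }
  ## seed clique over cores
  if (length(coreIdx) >= 2L) {
    cl <- t(utils::combn(coreIdx, 2L))
    addEdges(cl[, 1], cl[, 2])
  }
  deg <- integer(n)
  deg[coreIdx] <- length(coreIdx) - 1L
  bag <- rep(coreIdx, deg[coreIdx] + 1L)  # +1 keeps zero-degree reachable
  existing <- coreIdx
  others <- setdiff(seq_len(n), coreIdx)
  others <- others[sample.int(length(others))]
  for (v in others) {
    excl <- if (avoidCores[v]) coreIdx else integer()
    tg <- .paTargets(bag, min(m, length(existing)), excl, existing)
    if (length(tg)) {
      addEdges(rep.int(v, length(tg)), tg)
      deg[v] <- deg[v] + length(tg)
      deg[tg] <- deg[tg] + 1L
      bag <- c(bag, rep.int(v, length(tg)), tg)
    }
    existing <- c(existing, v)
    bag <- c(bag, v)
  }
  ## every modulator gets at least one core edge
  el0 <- do.call(rbind, edges[seq_len(ne)])
  adjCore <- unique(c(el0[el0[, 2] %in% coreIdx, 1],
                      el0[el0[, 1] %in% coreIdx, 2]))
  for (v in which(isModulator)) {
    if (!(v %in% adjCore)) {
      tgt <- coreIdx[sample.int(length(coreIdx), 1L)]
      addEdges(v, tgt)
      deg[v] <- deg[v] + 1L; deg[tgt] <- deg[tgt] + 1L
    }
  }
  ## promiscuous synthetic ubiquitin
  ubcIdx <- n + 1L
  nUbc <- ceiling(0.3 * n)
  ubcTargets <- sample.int(n, nUbc)
  addEdges(rep.int(ubcIdx, nUbc), ubcTargets)
  ## top-up: cores must reach the 90th percentile of all degrees
  degAll <- c(deg, nUbc)
  degAll[ubcTargets] <- degAll[ubcTargets] + 1L
  eligible <- which(!avoidCores & !truth$coreFlag)
  for (it in 1:50) {
    q90 <- stats::quantile(degAll, 0.9, names = FALSE)
    low <- coreIdx[degAll[coreIdx] < q90]
    if (!length(low)) break
    for (v in low) {
      k <- ceiling(q90 - degAll[v])
      tg <- eligible[sample.int(length(eligible), min(k, length(eligible)))]
      addEdges(rep.int(v, length(tg)), tg)
      degAll[v] <- degAll[v] + length(tg)
      degAll[tg] <- degAll[tg] + 1L
    }
  }
  el <- do.call(rbind, edges[seq_len(ne)])
  nodeNames <- c(genes, "UBC_SYN")
  g <- igraph::graph_from_edgelist(
    cbind(nodeNames[el[, 1]], nodeNames[el[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(nodeNames, igraph::V(g)$name)),
    name = setdiff(nodeNames, igraph::V(g)$name))
  g <- igraph::simplify(g)
  net <- newInteractionNetwork(g)
  ## construction guarantees, asserted
  stopifnot(all(igraph::degree(net@graph)[matchSymbols(net, genes[coreIdx])] >=
                stats::quantile(igraph::degree(net@graph), 0.9)))
  net
}

#' Generate annotation sets with planted enrichment
#'
#' Terms of the configured sizes are drawn from the gene universe.  Terms
#' with planted odds > 1 oversample DE genes by sequential weighted draws
#' (weight = odds for DE genes), i.e. term membership follows a Wallenius
#' noncentral hypergeometric law.  The first unenriched term of size >= 20 is
#' drawn from the longest length-quartile to exercise the bias correction.
#' With \code{foldChange = 1} all odds collapse to 1 and no term is flagged
#' enriched.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param truth ground truth from [genCounts()].
#' @return list with \code{sets} (named list, GMT-compatible) and \code{info}
#'   (data.frame with term, size, odds, enriched, longBiased, source).
#' @export
genAnnotations <- function(cfg, truth) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (nrow(truth) != cfg@nGenes)
    stop("gene universe of `truth` does not match `cfg`")
  set.seed(cfg@seed + 2L)
  genes <- truth$gene
  deAny <- truth$deStatusA != "none" | truth$deStatusB != "none"
  odds <- cfg@termOdds
  if (cfg@foldChange <= 1 || !any(deAny)) odds <- rep(1, length(odds))
  sizes <- cfg@termSizes
  longIdx <- which(truth$length >= stats::quantile(truth$length, 0.75))
  longTerm <- which(odds == 1 & sizes >= 20L)[1]
  sets <- vector("list", length(sizes))
  longBiased <- logical(length(sizes))
  for (i in seq_along(sizes)) {
    if (odds[i] > 1) {
      w <- ifelse(deAny, odds[i], 1)
      sets[[i]] <- genes[sample.int(length(genes), sizes[i], prob = w)]
    } else if (!is.na(longTerm) && i == longTerm) {
      sets[[i]] <- genes[longIdx[sample.int(length(longIdx), sizes[i])]]
      longBiased[i] <- TRUE
    } else {
      sets[[i]] <- genes[sample.int(length(genes), sizes[i])]
    }
  }
  names(sets) <- sprintf("TERM%03d", seq_along(sizes))
  info <- data.frame(term = names(sets), size = sizes, odds = odds,
                     enriched = odds > 1, longBiased = longBiased,
                     source = "GO")
  list(sets = sets, info = info)
}

#' Generate a synthetic exon table
#'
#' Genes laid out on one chromosome with multi-exon transcripts; a configured
#' number of adjacent protein-coding gene pairs overlap (their boundary exons
#' share an interval), so ambiguous reads can be constructed.  A fraction of
#' genes is non-protein-coding to exercise the biotype filter.
#'
#' @param nGenes number of genes.
#' @param nOverlapPairs number of overlapping adjacent protein-coding pairs.
#' @param fracNoncoding fraction of genes with biotype "lincRNA".
#' @param seed RNG seed.
#' @return data.frame in the internal exon-table layout (1-based closed).
#' @export
genExonTable <- function(nGenes = 20L, nOverlapPairs = 2L,
                         fracNoncoding = 0.15, seed = 1L) {
  set.seed(seed)
  stopifnot(nGenes >= 2L * nOverlapPairs + 2L)
  recs <- list()
  cursor <- 1000L
  prevEnd <- NA_integer_; prevLastExonStart <- NA_integer_
  overlapWith <- rep(FALSE, nGenes)
  if (nOverlapPairs > 0) {
    firsts <- seq(2L, by = 2L, length.out = nOverlapPairs)
    overlapWith[firsts + 1L] <- TRUE  # gene i overlaps gene i-1
  }
  noncoding <- stats::runif(nGenes) < fracNoncoding
  noncoding[overlapWith | c(overlapWith[-1], FALSE)] <- FALSE
  for (g in seq_len(nGenes)) {
    gid <- sprintf("GENE%03d", g)
    if (overlapWith[g] && !is.na(prevLastExonStart)) {
      start <- prevLastExonStart + 50L  # first exon overlaps previous gene
    } else {
      start <- cursor + sample(500:1500, 1L)
    }
    nEx <- sample(2:5, 1L)
    widths <- sample(100:300, nEx, replace = TRUE)
    gaps <- sample(50:200, nEx, replace = TRUE)
    exStart <- integer(nEx); exEnd <- integer(nEx)
    pos <- start
    for (e in seq_len(nEx)) {
      exStart[e] <- pos
      exEnd[e] <- pos + widths[e] - 1L
      pos <- exEnd[e] + gaps[e] + 1L
    }
    strand <- sample(c("+", "-"), 1L)
    biotype <- if (noncoding[g]) "lincRNA" else "protein_coding"
    nTx <- sample(1:3, 1L)
    for (t in seq_len(nTx)) {
      keep <- if (t == 1L) seq_len(nEx) else
        sort(sample.int(nEx, max(1L, nEx - sample(0:2, 1L))))
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = sprintf("%s.T%d", gid, t),
        chrom = "chr1", start = exStart[keep], end = exEnd[keep],
        strand = strand, biotype = biotype)
    }
    prevEnd <- max(exEnd); prevLastExonStart <- exStart[nEx]
    cursor <- max(cursor, prevEnd)
  }
  do.call(rbind, recs)
}

#' Generate alignment intervals with truth labels
#'
#' Places contiguous reads over a chimeric gene model: "countable" reads fall
#' entirely inside exonic bases unique to one gene, "ambiguous" reads inside
#' exonic bases shared by two genes, "multimapped" reads duplicate countable
#' positions with multiplicity > 1, and "no_feature" reads fall between
#' genes.  Truth labels (and the source gene of countable reads) are recorded
#' so the counting stage can be checked exactly.
#'
#' @param model a \linkS4class{ChimericGeneModel}.
#' @param depth expected countable reads per gene (Poisson).
#' @param readLen read length in bp.
#' @param nMultimapped,nNoFeature numbers of planted multi-mapped and
#'   no-feature reads.
#' @param nAmbiguousPerOverlap ambiguous reads per overlapping gene pair.
#' @param seed RNG seed.
#' @return a \code{GRanges} with metadata read_id, multiplicity, truth and
#'   truthGene (NA except for countable/multimapped reads).
#' @export
genAlignments <- function(model, depth = 50, readLen = 36L,
                          nMultimapped = 10L, nNoFeature = 10L,
                          nAmbiguousPerOverlap = 5L, seed = 1L) {
  stopifnot(is(model, "ChimericGeneModel"))
  set.seed(seed)
  ex <- model@exons
  flat <- unlist(ex, use.names = FALSE)
  flat$gene <- rep(names(ex), lengths(ex))
  allEx <- GenomicRanges::reduce(flat, ignore.strand = TRUE)
  cov <- GenomicRanges::coverage(flat)
  shared <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L),
                                   seqinfo = GenomicRanges::seqinfo(flat))
  uniq <- GenomicRanges::setdiff(allEx, shared, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(uniq, flat, ignore.strand = TRUE)
  uniqGene <- rep(NA_character_, length(uniq))
  uniqGene[S4Vectors::queryHits(hit)] <- flat$gene[S4Vectors::subjectHits(hit)]

  placeIn <- function(gr, n) {
    w <- GenomicRanges::width(gr)
    ok <- which(w >= readLen)
    if (!length(ok) || n == 0L) return(GenomicRanges::GRanges())
    pickIdx <- ok[sample.int(length(ok), n, replace = TRUE,
                             prob = w[ok] - readLen + 1)]
    st <- GenomicRanges::start(gr)[pickIdx] +
      floor(stats::runif(n) * (w[pickIdx] - readLen + 1))
    out <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr)[pickIdx],
      IRanges::IRanges(st, width = readLen), strand = "+")
    out$srcIdx <- pickIdx
    out
  }

  reads <- list()
  for (g in names(ex)) {
    regions <- uniq[!is.na(uniqGene) & uniqGene == g]
    n <- stats::rpois(1L, depth)
    r <- placeIn(regions, n)
    if (length(r)) {
      r$truth <- "countable"; r$truthGene <- g
      reads[[length(reads) + 1L]] <- r
    }
  }
  if (length(shared) && nAmbiguousPerOverlap > 0L) {
    r <- placeIn(shared, nAmbiguousPerOverlap * length(shared))
    if (length(r)) {
      r$truth <- "ambiguous"; r$truthGene <- NA_character_
      reads[[length(reads) + 1L]] <- r
    }
  }
  countable <- do.call(c, unname(reads[vapply(reads, function(x)
    x$truth[1] == "countable", TRUE)]))
  if (length(countable) && nMultimapped > 0L) {
    idx <- sample.int(length(countable), min(nMultimapped, length(countable)))
    mm <- countable[idx]
    mm$truth <- "multimapped"
    reads[[length(reads) + 1L]] <- mm
  }
  gaps <- GenomicRanges::gaps(allEx + 100L)
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  if (length(gaps) && nNoFeature > 0L) {
    r <- placeIn(gaps, nNoFeature)
    if (length(r)) {
      r$truth <- "no_feature"; r$truthGene <- NA_character_
      reads[[length(reads) + 1L]] <- r
    }
  }
  aln <- do.call(c, unname(reads))
  aln$srcIdx <- NULL
  aln$multiplicity <- ifelse(aln$truth == "multimapped",
                             sample(2:3, length(aln), replace = TRUE), 1L)
  aln$read_id <- sprintf("read%05d", seq_along(aln))
  aln
}

#' Write every synthetic artifact of one simulation to a directory
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the generated objects.
#' @export
writeSimulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- genCounts(cfg)
  net <- genNetwork(cfg, sim$truth)
  ann <- genAnnotations(cfg, sim$truth)
  writeCountsTSV(sim$se, file.path(dir, "counts.tsv"))
  utils::write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSIF(net, file.path(dir, "network.sif"))
  writeEdgeTSV(net, file.path(dir, "network.tsv"))
  writeGMT(ann$sets, file.path(dir, "annotations.gmt"),
           description = ann$info$source)
  writeLines(sim$truth$gene[sim$truth$coreFlag], file.path(dir, "cores.txt"))
  invisible(list(sim = sim, net = net, ann = ann))
}
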