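## Chimeric gene models and read counting: per-gene union of protein-coding
## transcript exons, the 50%-exon expression filter, and
## intersection-nonempty counting of contiguous alignment intervals with
## multi-mapped and multi-gene reads discarded.

#' Build the chimeric per-gene exon model
#'
#' Merges the exons of all protein-coding transcripts of each gene into a
#' set of disjoint sorted intervals.  Non-protein-coding transcripts are
#' dropped; genes without any protein-coding transcript are absent from the
#' model.  Counting downstream is strand-agnostic, so strands are erased.
#'
#' @param exons exon records as returned by [readExonTable()],
#'   [readExonGTF()] or [genExonTable()]: a data.frame with gene_id,
#'   transcript_id, chrom, start, end, strand, biotype (1-based closed).
#' @return a \linkS4class{ChimericGeneModel}.
#' @examples
#' ex <- data.frame(gene_id = "g", transcript_id = c("t1", "t1", "t2"),
#'                  chrom = "chr1", start = c(100, 300, 150),
#'                  end = c(199, 399, 249), strand = "+",
#'                  biotype = "protein_coding")
#' exonicLength(buildChimericModel(ex))
#' @export
buildChimericModel <- function(exons) {
  bad <- which(exons$end < exons$start)
  if (length(bad))
    stop("exon record with end < start: gene ", exons$gene_id[bad[1]],
         ", transcript ", exons$transcript_id[bad[1]])
  exons <- exons[exons$biotype == "protein_coding", , drop = FALSE]
  if (!nrow(exons)) stop("no protein-coding transcripts in the exon table")
  gr <- GenomicRanges::GRanges(exons$chrom,
          IRanges::IRanges(exons$start, exons$end), strand = "*")
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(gr, exons$gene_id), ignore.strand = TRUE)
  new("ChimericGeneModel", exons = grl)
}

#' @describeIn buildChimericModel total merged exonic length per gene.
#' @param x a \linkS4class{ChimericGeneModel}.
#' @export
setMethod("exonicLength", "ChimericGeneModel", function(x) {
  out <- sum(GenomicRanges::width(x@exons))
  stats::setNames(as.integer(out), names(x@exons))
})

#' @describeIn buildChimericModel number of merged exons per gene.
#' @export
setMethod("exonCount", "ChimericGeneModel", function(x) {
  stats::setNames(lengths(x@exons), names(x@exons))
})

## flat GRanges of all merged exons with a gene column
.flatExons <- function(model) {
  ex <- model@exons
  flat <- unlist(ex, use.names = FALSE)
  flat$gene <- rep(names(ex), lengths(ex))
  flat
}

#' Expression filter: reads in at least 50% of a gene's merged exons
#'
#' A gene is dropped if and only if, in \emph{every} sample, strictly fewer
#' than half of its merged exons contain at least one overlapping read.
#' Exactly 50% coverage keeps the gene, and coverage in a single sample is
#' enough to rescue it.
#'
#' @param model a \linkS4class{ChimericGeneModel}.
#' @param alignmentsBySample list of \code{GRanges} of alignment intervals,
#'   one element per sample.
#' @return list with character vectors \code{kept} and \code{dropped}.
#' @export
exonCoverageFilter <- function(model, alignmentsBySample) {
  stopifnot(is(model, "ChimericGeneModel"))
  if (length(model@exons) == 0L) stop("empty gene model")
  if (!length(alignmentsBySample)) stop("need at least one sample")
  flat <- .flatExons(model)
  nEx <- exonCount(model)
  expressed <- rep(FALSE, length(nEx))
  names(expressed) <- names(nEx)
  for (aln in alignmentsBySample) {
    hit <- GenomicRanges::countOverlaps(flat, aln, ignore.strand = TRUE) > 0L
    frac <- tapply(hit, flat$gene, mean)
    expressed[names(frac)] <- expressed[names(frac)] | frac >= 0.5
  }
  list(kept = names(expressed)[expressed],
       dropped = names(expressed)[!expressed])
}

#' Count alignment intervals per gene (intersection-nonempty)
#'
#' Multi-mapped records (multiplicity > 1) are discarded.  For each
#' remaining read, the assigned gene set is the intersection, over read
#' bases covered by any merged exon, of the per-base gene sets (bases
#' touching no exon are ignored).  Reads whose assignment resolves to
#' exactly one gene increment that gene; reads overlapping exons of two or
#' more genes with no unique resolution, and reads touching no exon at all,
#' are discarded.  Records on chromosomes absent from the model are skipped
#' with a warning.
#'
#' @param model a \linkS4class{ChimericGeneModel} (after filtering).
#' @param alignments a \code{GRanges} with a \code{multiplicity} metadata
#'   column (absent means all unique).
#' @return named integer vector of counts, one per model gene, plus an
#'   attribute \code{discarded} with the numbers of multimapped, ambiguous
#'   and no_feature reads.
#' @export
countReads <- function(model, alignments) {
  stopifnot(is(model, "ChimericGeneModel"))
  flat <- .flatExons(model)
  genes <- names(model@exons)
  counts <- stats::setNames(integer(length(genes)), genes)
  mult <- if (is.null(alignments$multiplicity)) rep(1L, length(alignments))
          else alignments$multiplicity
  nMulti <- sum(mult > 1L)
  aln <- alignments[mult <= 1L]
  offChrom <- !(as.character(GenomicRanges::seqnames(aln)) %in%
                as.character(GenomicRanges::seqnames(flat)))
  if (any(offChrom)) {
    warning(sum(offChrom),
            " record(s) on chromosomes absent from the model were skipped")
    aln <- aln[!offChrom]
  }
  hits <- GenomicRanges::findOverlaps(aln, flat, ignore.strand = TRUE)
  geneHits <- S4Vectors::splitAsList(flat$gene[S4Vectors::subjectHits(hits)],
                                     factor(S4Vectors::queryHits(hits),
                                            levels = seq_along(aln)))
  geneHits <- lapply(geneHits, unique)
  nGenesHit <- lengths(geneHits)
  nNoFeature <- sum(nGenesHit == 0L)
  single <- which(nGenesHit == 1L)
  if (length(single)) {
    tab <- table(unlist(geneHits[single]))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  nAmbiguous <- 0L
  for (q in which(nGenesHit >= 2L)) {
    ## base-resolution intersection over feature-covered bases
    r <- aln[q]
    cand <- geneHits[[q]]
    pieces <- GenomicRanges::disjoin(
      IRanges::pintersect(
        IRanges::findOverlapPairs(flat[flat$gene %in% cand], r,
                                  ignore.strand = TRUE)))
    covering <- lapply(seq_along(pieces), function(i) {
      ov <- GenomicRanges::findOverlaps(pieces[i], flat, type = "within",
                                        ignore.strand = TRUE)
      unique(flat$gene[S4Vectors::subjectHits(ov)])
    })
    assigned <- Reduce(intersect, covering)
    if (length(assigned) == 1L)
      counts[assigned] <- counts[assigned] + 1L
    else nAmbiguous <- nAmbiguous + 1L
  }
  attr(counts, "discarded") <- c(multimapped = nMulti,
                                 ambiguous = nAmbiguous,
                                 no_feature = nNoFeature)
  counts
}
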