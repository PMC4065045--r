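mkExons <- function(gene, tx, starts, ends, chrom = "chr1", strand = "+",
                    biotype = "protein_coding") {
  data.frame(gene_id = gene, transcript_id = tx, chrom = chrom,
             start = starts, end = ends, strand = strand, biotype = biotype)
}

test_that("chimeric model merges transcript exons into disjoint intervals", {
  ## 0-based half-open {[100,200),[300,400)} + {[150,250)} on disk is
  ## 1-based closed {[101,200],[301,400]} + {[151,250]} internally
  ex <- rbind(mkExons("g1", "t1", c(101L, 301L), c(200L, 400L)),
              mkExons("g1", "t2", 151L, 250L))
  model <- buildChimericModel(ex)
  gr <- model@exons[["g1"]]
  expect_equal(GenomicRanges::start(gr), c(101L, 301L))
  expect_equal(GenomicRanges::end(gr), c(250L, 400L))
  expect_equal(unname(exonicLength(model)["g1"]), 250L)
  expect_equal(unname(exonCount(model)["g1"]), 2L)
})

test_that("single transcript model is the identity; idempotent on own output", {
  ex <- mkExons("g1", "t1", c(10L, 100L, 500L), c(50L, 200L, 620L))
  m1 <- buildChimericModel(ex)
  gr <- m1@exons[["g1"]]
  expect_equal(GenomicRanges::start(gr), c(10L, 100L, 500L))
  ## feed the merged model back through the builder
  back <- data.frame(gene_id = "g1",
                     transcript_id = "chimeric",
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = "+", biotype = "protein_coding")
  m2 <- buildChimericModel(back)
  expect_equal(GenomicRanges::ranges(m2@exons[["g1"]]),
               GenomicRanges::ranges(m1@exons[["g1"]]))
})

test_that("overlapping transcript tilings collapse to the base-pair union", {
  ## 3 transcripts tiling 1..300 in overlapping 150-bp exons
  ex <- rbind(mkExons("g1", "t1", 1L, 150L),
              mkExons("g1", "t2", 76L, 225L),
              mkExons("g1", "t3", 151L, 300L))
  model <- buildChimericModel(ex)
  ## brute-force base-pair marking oracle
  covered <- rep(FALSE, 400)
  for (i in seq_len(nrow(ex))) covered[ex$start[i]:ex$end[i]] <- TRUE
  expect_equal(unname(exonicLength(model)["g1"]), sum(covered))
  expect_equal(unname(exonCount(model)["g1"]), 1L)
})

test_that("non-protein-coding transcripts and malformed records are handled", {
  ex <- rbind(mkExons("g1", "t1", 10L, 50L),
              mkExons("g2", "t2", 100L, 150L, biotype = "lincRNA"))
  model <- buildChimericModel(ex)
  expect_identical(names(model@exons), "g1")
  bad <- mkExons("g3", "t3", 50L, 40L)
  expect_error(buildChimericModel(bad), "g3")
})

test_that("exon coverage filter drops only genes below 50% in every sample", {
  ex <- rbind(mkExons("g2ex", "t1", c(10L, 200L), c(100L, 300L)),
              mkExons("g4ex", "t2", c(1000L, 1200L, 1400L, 1600L),
                      c(1100L, 1300L, 1500L, 1700L)))
  model <- buildChimericModel(ex)
  read <- function(st) GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(st, width = 36), strand = "+")
  ## g2ex: reads in 1 of 2 exons (50%) in both samples -> kept (strict <50%)
  ## g4ex: reads in 1 of 4 exons (25%) in both samples -> dropped
  s1 <- c(read(20), read(1010))
  s2 <- c(read(30), read(1210))
  filt <- exonCoverageFilter(model, list(s1, s2))
  expect_identical(filt$kept, "g2ex")
  expect_identical(filt$dropped, "g4ex")
  ## one sample at 100% rescues a gene below 50% elsewhere
  s3 <- c(read(20), read(1010), read(1210), read(1410), read(1610))
  filt2 <- exonCoverageFilter(model, list(s1, s2, s3))
  expect_identical(filt2$dropped, character(0))
  expect_error(exonCoverageFilter(model, list()), "sample")
})

test_that("counting follows intersection-nonempty with discards", {
  ## genes A and B overlap in [200,260]
  ex <- rbind(mkExons("A", "tA", c(100L, 190L), c(160L, 260L)),
              mkExons("B", "tB", c(200L, 400L), c(300L, 500L)))
  model <- buildChimericModel(ex)
  gr <- function(st, w = 36L, mult = 1L, chrom = "chr1") {
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, width = w),
                                strand = "+")
    g$read_id <- paste0("r", st); g$multiplicity <- mult
    g
  }
  aln <- c(gr(110), gr(120), gr(210), gr(410), gr(130, mult = 3L),
           gr(700), gr(162, w = 20L))
  mixed <- suppressWarnings(c(aln, gr(10, chrom = "chrX")))  # seqlevel union
  expect_warning(counts <- countReads(model, mixed), "skipped")
  ## 110,120 -> A; 210 overlaps exons of both -> discarded; 410 -> B;
  ## mult=3 discarded; 700 is no-feature (162-181 sits in A's intron
  ## 161..189, also no-feature); chrX skipped
  expect_equal(unname(counts["A"]), 2L)
  expect_equal(unname(counts["B"]), 1L)
  disc <- attr(counts, "discarded")
  expect_equal(unname(disc["multimapped"]), 1L)
  expect_equal(unname(disc["ambiguous"]), 1L)
  expect_equal(unname(disc["no_feature"]), 2L)
  ## a read in the overlap of A and B but also covering A-only bases
  ## resolves to A (intersection over covered feature bases)
  res <- countReads(model, gr(190, w = 15L))
  expect_equal(unname(res["A"]), 1L)
})

test_that("synthetic alignments are counted exactly as the truth labels say", {
  ex <- genExonTable(nGenes = 15L, nOverlapPairs = 2L, seed = 3L)
  model <- buildChimericModel(ex)
  aln <- genAlignments(model, depth = 25, seed = 8L)
  counts <- countReads(model, aln)
  truthCounts <- table(aln$truthGene[aln$truth == "countable"])
  expect_equal(unname(counts[names(truthCounts)]),
               unname(as.integer(truthCounts)))
  expect_equal(sum(counts), sum(aln$truth == "countable"))
  ## independent base-pair-marking oracle on merged exons
  flat <- unlist(model@exons)
  exonDf <- data.frame(gene = names(flat),
                       chrom = as.character(GenomicRanges::seqnames(flat)),
                       start = GenomicRanges::start(flat),
                       end = GenomicRanges::end(flat))
  alnDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(aln)),
                      start = GenomicRanges::start(aln),
                      end = GenomicRanges::end(aln),
                      multiplicity = aln$multiplicity)
  oracle <- oracleCountReads(exonDf, alnDf)
  expect_equal(unname(counts[names(oracle)]), unname(oracle))
  ## conservation: total counts never exceed unique-multiplicity records
  expect_lte(sum(counts), sum(aln$multiplicity == 1L))
})

test_that("counting is strand-agnostic", {
  ex <- genExonTable(nGenes = 10L, nOverlapPairs = 1L, seed = 5L)
  model <- buildChimericModel(ex)
  aln <- genAlignments(model, depth = 15, seed = 9L)
  flipped <- aln
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(aln)) == "+", "-", "+")
  expect_equal(countReads(model, aln), countReads(model, flipped))
})

test_that("exon tables round-trip through TSV with the coordinate shift", {
  ex <- genExonTable(nGenes = 6L, nOverlapPairs = 1L, seed = 2L)
  f <- withr::local_tempfile()
  writeExonTable(ex, f)
  back <- readExonTable(f)
  expect_equal(back$start, ex$start)
  expect_equal(back$end, ex$end)
  onDisk <- utils::read.delim(f)
  expect_equal(onDisk$start, ex$start - 1L)  # 0-based half-open on disk
})
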