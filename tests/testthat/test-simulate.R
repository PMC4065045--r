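test_that("count generation is deterministic and respects planted fractions", {
  cfg <- simulationConfig(nGenes = 5000L, fracSharedDE = 0.02,
                          fracSubsetDE = 0.01, foldChange = 4, seed = 7L)
  sim1 <- genCounts(cfg)
  sim2 <- genCounts(cfg)
  expect_identical(SummarizedExperiment::assay(sim1$se),
                   SummarizedExperiment::assay(sim2$se))
  expect_identical(as.data.frame(sim1$truth), as.data.frame(sim2$truth))
  ## floor rule: 100 shared + 50 subset-specific = 150 planted per subset
  tr <- sim1$truth
  expect_equal(sum(tr$deStatusA != "none"), 150L)
  expect_equal(sum(tr$deStatusB != "none"), 150L)
  expect_equal(sum(tr$deStatusA != "none" & tr$deStatusB != "none"), 100L)
  ## cores are never planted
  expect_true(all(tr$deStatusA[tr$coreFlag] == "none"))
  ## modulators are subset-specific DE genes of their subset
  mA <- tr$modulatorOf == "A" & !is.na(tr$modulatorOf)
  expect_true(all(tr$deStatusA[mA] != "none" & tr$deStatusB[mA] == "none"))
})

test_that("fold change 1 plants nothing and null DE fraction stays nominal", {
  cfg <- tinyConfig(foldChange = 1, nModulatorsPerSubset = 0L,
                    lengthBiasStrength = 0, seed = 21L)
  sim <- genCounts(cfg)
  tr <- sim$truth
  expect_true(all(tr$deStatusA == "none"))
  expect_true(all(tr$deStatusB == "none"))
  expect_true(all(is.na(tr$modulatorOf)))
  ann <- genAnnotations(cfg, tr)
  expect_false(any(ann$info$enriched))
})

test_that("generated network honours the planted topology guarantees", {
  cfg <- simulationConfig(nGenes = 100L, nCore = 6L,
                          nModulatorsPerSubset = 1L, netAttachM = 2L,
                          seed = 5L)
  sim <- genCounts(cfg)
  net <- genNetwork(cfg, sim$truth)
  g <- asIgraph(net)
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  ## at least m edges per non-clique node
  nClique <- cfg@nCore
  expect_gte(igraph::ecount(g), 2 * (100 - nClique))
  deg <- igraph::degree(g)
  expect_gte(deg[["UBC_SYN"]], ceiling(0.3 * cfg@nGenes))
  cores <- toupper(sim$truth$gene[sim$truth$coreFlag])
  expect_true(all(deg[cores] >= stats::quantile(deg, 0.9)))
  ## every modulator adjacent to >= 1 core
  mods <- toupper(sim$truth$gene[!is.na(sim$truth$modulatorOf)])
  for (m in mods) {
    nb <- toupper(names(igraph::neighbors(g, m)))
    expect_true(any(nb %in% cores))
  }
  ## conservation: every gene appears in the network node set
  expect_true(all(toupper(sim$truth$gene) %in% igraph::V(g)$name))
  ## universe mismatch is an error
  expect_error(genNetwork(cfg, sim$truth[-1, ]), "universe")
})

test_that("degree distribution of the default network is heavy-tailed", {
  ## frozen-seed regression on the default 5000-gene instance
  cfg <- simulationConfig()
  sim <- genCounts(cfg)
  net <- genNetwork(cfg, sim$truth)
  deg <- igraph::degree(asIgraph(net))
  expect_gt(max(deg), 10 * stats::median(deg))
})

test_that("annotation terms have the configured sizes and planted enrichment", {
  cfg <- simulationConfig(nGenes = 5000L, seed = 13L,
                          termSizes = c(8L, 50L, 50L), termOdds = c(1, 6, 1))
  sim <- genCounts(cfg)
  ann <- genAnnotations(cfg, sim$truth)
  expect_equal(unname(lengths(ann$sets)), c(8L, 50L, 50L))
  expect_identical(ann$info$enriched, c(FALSE, TRUE, FALSE))
  ## odds-1 terms are never flagged enriched
  expect_true(all(!ann$info$enriched[ann$info$odds == 1]))
  ## the planted long-biased term samples from the longest quartile
  long <- ann$info$term[ann$info$longBiased]
  expect_length(long, 1L)
  q75 <- stats::quantile(sim$truth$length, 0.75)
  expect_true(all(sim$truth[ann$sets[[long]], "length"] >= q75))
})

test_that("enriched-term membership follows the biased draw expectation", {
  ## conditions: odds 6, term size 50, 500 DE of 5000; the sequential
  ## weighted draw has expectation ~19 DE genes in the term
  n <- 5000L
  de <- rep(c(TRUE, FALSE), c(500L, n - 500L))
  w <- ifelse(de, 6, 1)
  set.seed(99)
  draws <- vapply(seq_len(2000L), function(i)
    sum(de[sample.int(n, 50L, prob = w)]), numeric(1))
  ## closed-form oracle: the Wallenius mean equation
  ## (1 - mu/m1)^(1/w) = 1 - (n.draw - mu)/m2 has root ~19.8
  root <- stats::uniroot(function(mu)
    (1 - mu / 500)^(1 / 6) - (1 - (50 - mu) / 4500), c(1, 49))$root
  expect_lt(abs(mean(draws) - root), 0.3)
  expect_gt(root, 18.5); expect_lt(root, 20.5)
  ## a generated enriched term of size 50 falls inside the oracle spread
  cfg <- simulationConfig(nGenes = n, seed = 31L,
                          termSizes = c(50L), termOdds = c(6))
  sim <- genCounts(cfg)
  ann <- genAnnotations(cfg, sim$truth)
  deAny <- sim$truth$deStatusA != "none" | sim$truth$deStatusB != "none"
  got <- sum(ann$sets[[1]] %in% sim$truth$gene[deAny])
  ## planted DE here is 200 of 5000, not 500: rescale oracle by simulation
  set.seed(100)
  draws2 <- vapply(seq_len(2000L), function(i)
    sum(deAny[sample.int(n, 50L, prob = ifelse(deAny, 6, 1))]), numeric(1))
  expect_gte(got, stats::quantile(draws2, 0.001))
  expect_lte(got, stats::quantile(draws2, 0.999))
})

test_that("synthetic alignments carry correct truth labels", {
  ex <- genExonTable(nGenes = 15L, nOverlapPairs = 2L, seed = 3L)
  model <- buildChimericModel(ex)
  aln <- genAlignments(model, depth = 20, seed = 4L)
  expect_setequal(unique(aln$truth),
                  c("countable", "ambiguous", "multimapped", "no_feature"))
  expect_true(all(aln$multiplicity[aln$truth == "multimapped"] > 1L))
  expect_true(all(aln$multiplicity[aln$truth != "multimapped"] == 1L))
  flat <- unlist(model@exons)
  ## countable reads sit inside exons of their truth gene
  cr <- aln[aln$truth == "countable"]
  ov <- GenomicRanges::countOverlaps(cr, flat, type = "within",
                                     ignore.strand = TRUE)
  expect_true(all(ov >= 1L))
  ## no_feature reads touch no exon
  nf <- aln[aln$truth == "no_feature"]
  expect_true(all(GenomicRanges::countOverlaps(nf, flat,
                                               ignore.strand = TRUE) == 0L))
})

test_that("simulation bundle round-trips through the plain-text formats", {
  cfg <- tinyConfig(seed = 17L)
  dir <- withr::local_tempdir()
  out <- writeSimulation(cfg, dir)
  se2 <- readCountsTSV(file.path(dir, "counts.tsv"))
  expect_equal(SummarizedExperiment::assay(se2, "counts"),
               SummarizedExperiment::assay(out$sim$se, "counts"))
  expect_equal(SummarizedExperiment::colData(se2)$subset,
               c("A", "A", "B", "B"))
  sets <- readGMT(file.path(dir, "annotations.gmt"))
  expect_identical(lapply(sets, sort),
                   lapply(out$ann$sets, sort)[names(sets)])
  edges <- readInteractions(file.path(dir, "network.sif"))
  net2 <- cleanNetwork(edges, exclusions = character())
  ## SIF stores edges, so the edge sets must agree exactly
  expect_equal(igraph::ecount(asIgraph(net2)), igraph::ecount(asIgraph(out$net)))
  expect_true(all(networkNodes(net2) %in% networkNodes(out$net)))
})
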