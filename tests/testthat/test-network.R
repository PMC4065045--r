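test_that("cleaning deduplicates, drops self-loops and excluded symbols", {
  edges <- data.frame(from = c("A", "B", "A"), to = c("B", "A", "A"))
  net <- cleanNetwork(edges, exclusions = character())
  expect_setequal(networkNodes(net), c("A", "B"))
  expect_equal(igraph::ecount(asIgraph(net)), 1L)
  ## exclusion removes the node and its incident edges, nothing else
  edges2 <- data.frame(from = c("A", "Ubc", "B"), to = c("B", "A", "C"))
  net2 <- cleanNetwork(edges2)             # default exclusion: Ubc
  expect_setequal(networkNodes(net2), c("A", "B", "C"))
  expect_equal(igraph::ecount(asIgraph(net2)), 2L)
  ## case-insensitive matching with case-preserving display
  edges3 <- data.frame(from = c("Tlr4", "TLR4"), to = c("Myd88", "Traf6"))
  net3 <- cleanNetwork(edges3, exclusions = character())
  expect_setequal(networkNodes(net3), c("Tlr4", "Myd88", "Traf6"))
  ## cleaning is idempotent and never grows the graph
  cfg <- tinyConfig(seed = 19L)
  sim <- genCounts(cfg)
  g0 <- genNetwork(cfg, sim$truth)
  c1 <- cleanNetwork(g0, exclusions = c("Ubc", "UBC_SYN"))
  c2 <- cleanNetwork(c1, exclusions = c("Ubc", "UBC_SYN"))
  expect_false("UBC_SYN" %in% networkNodes(c1))
  expect_identical(sort(networkNodes(c1)), sort(networkNodes(c2)))
  expect_equal(igraph::ecount(asIgraph(c1)), igraph::ecount(asIgraph(c2)))
  expect_lte(igraph::vcount(asIgraph(c1)), igraph::vcount(asIgraph(g0)))
  ## malformed input names the line
  f <- withr::local_tempfile(lines = c("A pp B", "broken"))
  expect_error(readInteractions(f, format = "sif"), "line 2")
})

test_that("first-order expansion returns seeds plus direct partners", {
  ## star graph, seed = centre -> whole graph
  star <- data.frame(from = rep("hub", 4), to = paste0("leaf", 1:4))
  net <- cleanNetwork(star, exclusions = character())
  ex <- firstOrderNeighborhood(net, "hub")
  expect_setequal(networkNodes(ex), c("hub", paste0("leaf", 1:4)))
  ## path A-B-C, seed A -> {A, B} with the single edge
  path <- data.frame(from = c("A", "B"), to = c("B", "C"))
  netP <- cleanNetwork(path, exclusions = character())
  exP <- firstOrderNeighborhood(netP, "A")
  expect_setequal(networkNodes(exP), c("A", "B"))
  expect_equal(igraph::ecount(asIgraph(exP)), 1L)
  ## absent seeds warn; all-absent errors
  expect_warning(firstOrderNeighborhood(netP, c("A", "ZZZ")), "absent")
  expect_error(suppressWarnings(firstOrderNeighborhood(netP, "ZZZ")),
               "none of the seeds")
  ## brute-force set oracle + monotonicity on a synthetic network
  cfg <- tinyConfig(seed = 37L)
  sim <- genCounts(cfg)
  net2 <- cleanNetwork(genNetwork(cfg, sim$truth),
                       exclusions = c("Ubc", "UBC_SYN"))
  g <- asIgraph(net2)
  cores <- sim$truth$gene[sim$truth$coreFlag]
  exp2 <- firstOrderNeighborhood(net2, cores)
  oracle <- union(toupper(cores),
                  toupper(unique(unlist(lapply(
                    igraph::adjacent_vertices(g, toupper(cores)), names)))))
  expect_setequal(toupper(networkNodes(exp2)), oracle)
  ## more seeds -> superset of nodes
  exp1 <- firstOrderNeighborhood(net2, cores[1:3])
  expect_true(all(networkNodes(exp1) %in% networkNodes(exp2)))
  ## every non-seed node is adjacent to >= 1 seed
  ge <- asIgraph(exp2)
  nonSeed <- setdiff(igraph::V(ge)$name, toupper(cores))
  for (v in nonSeed)
    expect_true(any(toupper(names(igraph::neighbors(ge, v))) %in%
                    toupper(cores)))
})

test_that("venn partition computes disjoint exhaustive classes", {
  p <- vennPartition(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(p@onlyA, "a")
  expect_setequal(p@shared, c("b", "c"))
  expect_setequal(p@onlyB, "d")
  expect_equal(p@pctA, 100 / 3)
  expect_equal(round(p@pctA), 33)
  ## identical sets -> both percentages 0
  pi <- vennPartition(letters[1:5], letters[1:5])
  expect_equal(pi@pctA, 0); expect_equal(pi@pctB, 0)
  ## the published set sizes: |A|=481, |B|=471, overlap 245
  A <- sprintf("gA%03d", 1:481)
  B <- c(A[1:245], sprintf("gB%03d", 1:226))
  pv <- vennPartition(A, B)
  expect_equal(length(pv@onlyA), 236)
  expect_equal(length(pv@onlyB), 226)
  expect_equal(round(pv@pctA), 49)
  expect_equal(round(pv@pctB), 48)
  ## property: classes disjoint and cover the union, on random sets
  set.seed(8)
  for (i in 1:20) {
    A <- sample(letters, sample(3:15, 1))
    B <- sample(letters, sample(3:15, 1))
    pp <- vennPartition(A, B)
    cls <- vennClasses(pp)
    expect_equal(sum(lengths(cls)), length(union(A, B)))
    expect_length(intersect(cls$onlyA, cls$shared), 0)
    expect_length(intersect(cls$onlyA, cls$onlyB), 0)
    expect_length(intersect(cls$shared, cls$onlyB), 0)
  }
})

test_that("modulator identification excludes seeds and matches planted truth", {
  ## tiny exact example: seeds {S}; edges S-X, S-Y; DE_A={X}, DE_B={X,Y}
  edges <- data.frame(from = c("S", "S"), to = c("X", "Y"))
  net <- cleanNetwork(edges, exclusions = character())
  exp1 <- firstOrderNeighborhood(net, "S")
  part <- findModulators(exp1, deA = "X", deB = c("X", "Y"), seeds = "S")
  expect_length(part@onlyA, 0)
  expect_setequal(part@shared, "X")
  expect_setequal(part@onlyB, "Y")
  ## DE sets disjoint from the neighbourhood -> all classes empty
  part0 <- findModulators(exp1, deA = "Q", deB = "R", seeds = "S")
  expect_equal(sum(lengths(vennClasses(part0))), 0)
  ## frozen-seed synthetic run: planted modulators that are called DE are
  ## all recovered, and recovered sets are dominated by planted truths
  cfg <- simulationConfig(nGenes = 2000L, nCore = 20L,
                          nModulatorsPerSubset = 15L, seed = 43L)
  sim <- genCounts(cfg)
  net2 <- cleanNetwork(genNetwork(cfg, sim$truth),
                       exclusions = c("Ubc", "UBC_SYN"))
  cores <- sim$truth$gene[sim$truth$coreFlag]
  expanded <- firstOrderNeighborhood(net2, cores)
  f <- medianRatioSizeFactors(sim$se)
  fit <- fitBlindDispersion(sim$se, f)
  cc <- deConfig(alpha = 0.05, useAdjusted = TRUE, minFoldChange = 2)
  deA <- deGenes(callDE(sim$se, "A", cc, f, fit))
  deB <- deGenes(callDE(sim$se, "B", cc, f, fit))
  part2 <- findModulators(expanded, deA, deB, cores)
  tr <- sim$truth
  for (s in c("A", "B")) {
    found <- if (s == "A") part2@setA else part2@setB
    planted <- tr$gene[!is.na(tr$modulatorOf) & tr$modulatorOf == s]
    called <- intersect(planted, if (s == "A") deA else deB)
    expect_true(all(called %in% found))          # full recall of called truths
    expect_gte(mean(found %in% planted), 0.7)    # precision bound
    expect_false(any(cores %in% found))          # seeds never reported
  }
})
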