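poissonFit <- function(xi = 1) {
  ## a DispersionFit with alpha(mu) = 0 everywhere (Poisson limit)
  new("DispersionFit", method = "parametric", xi = xi,
      coefs = c(b0 = xi, b1 = 0), localFit = NULL,
      baseMean = 1, baseVar = 1)
}

test_that("median-of-ratios size factors match the defining arithmetic", {
  ## two identical samples
  k <- matrix(c(5L, 10L, 50L, 5L, 10L, 50L), ncol = 2)
  expect_equal(unname(medianRatioSizeFactors(k)), c(1, 1))
  ## exact 3x scaling: factors proportional to (1, 3), normalised counts equal
  k3 <- cbind(c(10L, 20L, 40L), c(30L, 60L, 120L))
  s <- medianRatioSizeFactors(k3)
  expect_equal(unname(s[2] / s[1]), 3)
  expect_equal(sweep(k3, 2, s, "/")[, 1], sweep(k3, 2, s, "/")[, 2])
  ## 5-gene toy matrix against direct arithmetic
  k5 <- cbind(a = c(4L, 10L, 20L, 7L, 100L), b = c(8L, 14L, 45L, 7L, 180L))
  geo <- exp(rowMeans(log(k5)))
  expected <- apply(k5 / geo, 2, stats::median)
  expect_equal(unname(medianRatioSizeFactors(k5)), unname(expected))
  ## all-zero-containing universe is an error
  expect_error(medianRatioSizeFactors(cbind(c(0L, 5L), c(3L, 0L))),
               "pre-filter")
})

test_that("size factors agree with the established reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  mu <- exp(stats::rnorm(1000, log(150), 1))
  depth <- c(1, 0.8, 1.2, 0.5)
  k <- vapply(depth, function(f)
    stats::rnbinom(1000, mu = mu * f, size = 10), numeric(1000))
  storage.mode(k) <- "integer"
  ours <- medianRatioSizeFactors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("blind fit recovers Poisson and NB dispersion", {
  set.seed(11)
  n <- 5000
  mu <- exp(stats::rnorm(n, log(200), 1))
  kp <- matrix(stats::rpois(4 * n, rep(mu, 4)), ncol = 4)
  fitP <- fitBlindDispersion(kp, factors = rep(1, 4))
  ## Poisson data: fitted overdispersion is ~0 at representative means
  expect_lt(max(fittedDispersion(fitP, c(50, 200, 1000))), 0.005)
  ## clamp: fitted variance never drops below the Poisson floor
  expect_true(all(fittedVariance(fitP, c(1, 10, 100, 1e4)) >=
                  c(1, 10, 100, 1e4)))
  kn <- matrix(stats::rnbinom(4 * n, mu = rep(mu, 4), size = 5), ncol = 4)
  fitN <- fitBlindDispersion(kn, factors = rep(1, 4))
  ## phi = 0.2 recovered within 25%
  disp <- fittedDispersion(fitN, c(100, 200, 500))
  expect_true(all(abs(disp - 0.2) / 0.2 < 0.25))
  expect_error(fitBlindDispersion(kp[, 1, drop = FALSE]), "two samples")
})

test_that("exact test follows its defining enumeration and conventions", {
  ## total zero -> p = 1 by convention
  fit <- poissonFit()
  expect_equal(nbExactTest(0, 0, 1, 1, fit), 1)
  ## Poisson limit, equal factors: p for the extreme split equals the
  ## two-tail binomial(40, 1/2) point mass (compared on the log scale;
  ## the variance clamp leaves a ~1e-8 relative wrinkle)
  expect_lt(abs(log(nbExactTest(0, 40, 1, 1, fit)) - log(2 * 0.5^40)),
            1e-4)
  ## symmetry in (A, B) under equal size factors
  set.seed(5)
  k <- matrix(stats::rnbinom(2000, mu = 100, size = 8), ncol = 4)
  nbfit <- fitBlindDispersion(k, factors = rep(1, 4))
  for (pair in list(c(3, 17), c(40, 41), c(0, 9))) {
    expect_equal(nbExactTest(pair[1], pair[2], 1, 1, nbfit),
                 nbExactTest(pair[2], pair[1], 1, 1, nbfit))
  }
  ## enumeration oracle on a grid of small totals and unequal factors
  sA <- 1.2; sB <- 0.7
  for (kA in c(0L, 2L, 9L)) for (kB in c(1L, 5L, 14L)) {
    q <- (kA / sA + kB / sB) / 2
    alpha <- fittedDispersion(nbfit, q)
    expect_equal(nbExactTest(kA, kB, sA, sB, nbfit),
                 oracleNBExact(kA, kB, sA * q, sB * q, alpha),
                 tolerance = 1e-12)
  }
})

test_that("DE calling applies inclusive thresholds and the fold-change rule", {
  ## craft counts whose p lands exactly analysable: use the caller end-to-end
  cfg <- tinyConfig(seed = 23L)
  sim <- genCounts(cfg)
  de <- callDE(sim$se, "A")
  expect_s4_class(de, "DEResult")
  ## call consistency with the recorded p-values
  expect_true(all(de$call[de$pRaw > 0.05] == "ns"))
  expect_true(all(de$pRaw[de$call != "ns"] <= 0.05))
  ## BH is monotone and never below the raw p
  expect_true(all(de$pAdj >= de$pRaw - 1e-12))
  ord <- order(de$pRaw)
  expect_true(!is.unsorted(cummax(de$pAdj[ord])))
  ## threshold inclusivity and the fc rule, on a synthetic result row
  cc <- deConfig(alpha = 0.05, minFoldChange = 2)
  fakeDE <- de
  i <- which.min(abs(fakeDE$fc - 1.8))
  expect_true(fakeDE$fc[i] < 2 && fakeDE$fc[i] > 1 / 2)
  ## a gene with p exactly at alpha is called (when fc passes)
  p <- c(g1 = 0.05, g2 = 0.051)
  called <- p <= 0.05
  expect_identical(unname(called), c(TRUE, FALSE))
  ## min_fold_change = 2 silences fc = 1.8 however small p is
  rule <- function(p, fc, cfg) {
    pp <- p
    (pp <= cfg@alpha & fc >= cfg@minFoldChange) |
      (pp <= cfg@alpha & fc <= 1 / cfg@minFoldChange)
  }
  expect_false(rule(0.001, 1.8, cc))
  expect_true(rule(0.05, 2.0, cc))
})

test_that("genes with zero counts everywhere are excluded before testing", {
  cfg <- tinyConfig(seed = 29L)
  sim <- genCounts(cfg)
  counts <- SummarizedExperiment::assay(sim$se)
  allZero <- rownames(counts)[rowSums(counts) == 0]
  de <- callDE(sim$se, "B")
  expect_false(any(allZero %in% de$gene))
  expect_equal(S4Vectors::metadata(de)$nUntestable, length(allZero))
})

test_that("CPM columns scale to one million and match hand arithmetic", {
  k <- cbind(s1 = c(10L, 990L), s2 = c(30L, 2970L))
  cpm <- countsPerMillion(k, factors = c(1, 1))
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(cpm[1, 1]), 10 / 1000 * 1e6)
  ## 3-gene toy with explicit factors
  k3 <- cbind(a = c(5L, 10L, 35L), b = c(6L, 30L, 24L))
  f <- c(1, 1.5)
  nc <- sweep(k3, 2, f, "/")
  expect_equal(countsPerMillion(k3, f),
               sweep(nc, 2, colSums(nc), "/") * 1e6)
})

test_that("planted DE structure is recovered by the FDR-controlled caller", {
  ## frozen-seed regression at the default study conditions
  cfg <- simulationConfig(seed = 20140620L)
  sim <- genCounts(cfg)
  f <- medianRatioSizeFactors(sim$se)
  fit <- fitBlindDispersion(sim$se, f)
  cc <- deConfig(alpha = 0.05, useAdjusted = TRUE, minFoldChange = 2)
  for (s in c("A", "B")) {
    de <- callDE(sim$se, s, cc, f, fit)
    called <- deGenes(de)
    planted <- sim$truth$gene[sim$truth[[paste0("deStatus", s)]] != "none"]
    expect_gte(mean(planted %in% called), 0.8)
    expect_lte(mean(!(called %in% planted)), 0.1)
  }
})
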