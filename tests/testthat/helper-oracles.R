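## Independent brute-force oracles used across the suite.  These deliberately
## avoid the package's own code paths.

## base-pair-marking interval scan: per read, the set of genes whose merged
## exons cover each exon-covered base; intersection-nonempty assignment
oracleCountReads <- function(exonDf, alnDf) {
  genes <- unique(exonDf$gene)
  counts <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(alnDf))) {
    if (alnDf$multiplicity[i] > 1L) next
    bases <- alnDf$start[i]:alnDf$end[i]
    sets <- lapply(bases, function(b) {
      hit <- exonDf$gene[exonDf$chrom == alnDf$chrom[i] &
                         exonDf$start <= b & exonDf$end >= b]
      unique(hit)
    })
    sets <- sets[lengths(sets) > 0L]          # feature-covered bases only
    if (!length(sets)) next
    assigned <- Reduce(intersect, sets)
    if (length(assigned) == 1L)
      counts[assigned] <- counts[assigned] + 1L
  }
  counts
}

## full enumeration of the probability-sum exact NB test
oracleNBExact <- function(kA, kB, muA, muB, alpha) {
  S <- kA + kB
  if (S == 0L) return(1)
  dens <- function(x, mu) {
    if (alpha > 0) stats::dnbinom(x, mu = mu, size = 1 / alpha)
    else stats::dpois(x, mu)
  }
  a <- 0:S
  pr <- dens(a, muA) * dens(S - a, muB)
  obs <- dens(kA, muA) * dens(kB, muB)
  sum(pr[pr <= obs * (1 + 1e-7)]) / sum(pr)
}

## exhaustive hypergeometric overlap: enumerate all placements of list B
oracleOverlap <- function(N, nA, nB, k) {
  placements <- utils::combn(N, nB)
  overlaps <- colSums(placements <= nA)   # list A occupies items 1..nA
  mean(overlaps >= k)
}

## Wallenius biased-urn Monte-Carlo by the exponential race: drawing n items
## without replacement with odds w for the m1 white items is equivalent to
## taking the n smallest of Exp(w) (whites) and Exp(1) (others)
oracleWalleniusMC <- function(q, m1, m2, n, w, reps = 1e6, chunk = 1e5) {
  hits <- 0
  done <- 0
  while (done < reps) {
    r <- min(chunk, reps - done)
    e1 <- matrix(stats::rexp(m1 * r, rate = w), nrow = m1)
    e2 <- matrix(stats::rexp(m2 * r, rate = 1), nrow = m2)
    x <- vapply(seq_len(r), function(j) {
      thr <- sort.int(c(e1[, j], e2[, j]), partial = n)[n]
      sum(e1[, j] <= thr)
    }, numeric(1))
    hits <- hits + sum(x >= q)
    done <- done + r
  }
  hits / reps
}

## exhaustive best connected subgraph under the calibrated score
oracleBestModule <- function(net, z, calib) {
  g <- asIgraph(net)
  V <- igraph::vcount(g)
  stopifnot(V <= 12L)
  best <- -Inf
  bestSet <- NULL
  for (mask in seq_len(2^V - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(V) - 1L)) > 0)
    sg <- igraph::induced_subgraph(g, idx)
    if (!igraph::is_connected(sg)) next
    memb <- igraph::V(g)$display[idx]
    s <- moduleScore(scoreSubnetwork(memb, z, calib))
    if (s > best) {
      best <- s
      bestSet <- memb
    }
  }
  list(score = best, members = bestSet)
}

## small ready-made simulation shared by several tests
tinyConfig <- function(...) {
  args <- utils::modifyList(list(nGenes = 400L, nCore = 8L,
                                 nModulatorsPerSubset = 4L), list(...))
  do.call(simulationConfig, args)
}
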