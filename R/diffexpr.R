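## Single-replicate differential expression: median-of-ratios size factors,
## pooled ("blind") mean-variance estimation used fit-only, an exact
## negative binomial test conditioning on the pairwise total, DE calling
## with inclusive thresholds, and counts-per-million summaries.

.countsMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the gene's
#' count to its across-sample geometric mean.
#'
#' @param x count matrix (genes x samples) or a \code{SummarizedExperiment}.
#' @return named numeric vector of positive size factors.  A message is
#'   logged if their geometric mean strays more than 10% from 1.
#' @examples
#' k <- matrix(c(10, 20, 30, 30, 60, 90), ncol = 2)
#' medianRatioSizeFactors(k)  # c(1, 3) up to scale
#' @export
medianRatioSizeFactors <- function(x) {
  counts <- .countsMatrix(x)
  if (ncol(counts) < 2L) stop("need at least two samples")
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos))
    stop("no gene has nonzero counts in all samples; ",
         "pre-filter the count matrix before normalisation")
  logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
  s <- apply(counts[allPos, , drop = FALSE], 2L, function(k)
    exp(stats::median(log(k) - logGeo)))
  gm <- exp(mean(log(s)))
  if (abs(gm - 1) > 0.1)
    message("size factors have geometric mean ", signif(gm, 3),
            " (soft check: expected within ~10% of 1)")
  s
}

#' Fit the pooled ("blind") mean-variance trend
#'
#' All samples are treated as replicates of one another, regardless of
#' condition: per-gene pooled means and variances of the normalised counts
#' are computed across every sample, and a smooth variance function is
#' fitted to the (mean, variance) pairs.  Downstream tests use only the
#' fitted trend ("fit-only"); per-gene empirical variances never override
#' it.  This is what makes single-replicate testing possible, at the price
#' of conservativeness: condition effects inflate the pooled variances.
#'
#' The parametric fit models the expected sample variance on the common
#' scale as v(mu) = b0*mu + b1*mu^2 by gamma-family iteratively reweighted
#' least squares; b0 absorbs the shot-noise term (mean of 1/sizeFactor) and
#' b1 is the asymptotic dispersion.  The local fit is a loess of
#' log(variance) on log(mean).
#'
#' @param x count matrix or \code{SummarizedExperiment} (>= 2 samples).
#' @param factors size factors from [medianRatioSizeFactors()]; computed if
#'   missing.
#' @param method "parametric" (default) or "local".
#' @return a \linkS4class{DispersionFit}.
#' @export
fitBlindDispersion <- function(x, factors = NULL,
                               method = c("parametric", "local")) {
  method <- match.arg(method)
  counts <- .countsMatrix(x)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (is.null(factors)) factors <- medianRatioSizeFactors(counts)
  nc <- sweep(counts, 2L, factors, "/")
  mu <- rowMeans(nc)
  v <- rowSums((nc - mu)^2) / (ncol(nc) - 1L)
  xi <- mean(1 / factors)
  use <- mu > 0 & v > 0
  if (sum(use) < 10L) stop("too few genes with positive mean and variance")
  muf <- mu[use]; vf <- v[use]
  localFit <- NULL
  coefs <- c(b0 = NA_real_, b1 = NA_real_)
  if (method == "parametric") {
    irls <- function(mm, vv) {
      X <- cbind(mm, mm^2)
      beta <- c(xi, max(stats::median((vv - xi * mm) / mm^2), 1e-4))
      for (it in 1:25) {
        fitted <- pmax(drop(X %*% beta), 0.1 * xi * mm)
        w <- 1 / fitted^2                   # gamma-family working weights
        XtW <- t(X * w)
        betaNew <- drop(solve(XtW %*% X, XtW %*% vv))
        if (max(abs(betaNew - beta) / (abs(beta) + 1e-8)) < 1e-10) {
          beta <- betaNew; break
        }
        beta <- betaNew
      }
      beta
    }
    ## trim trend outliers (genes whose pooled variance is dominated by
    ## condition effects rather than noise) by MAD on the log residual
    keep <- rep(TRUE, length(muf))
    beta <- irls(muf, vf)
    for (round in 1:3) {
      fittedAll <- pmax(beta[1] * muf + beta[2] * muf^2, 1e-12)
      r <- log(vf) - log(fittedAll)
      md <- stats::median(r[keep]); s <- stats::mad(r[keep])
      keepNew <- abs(r - md) <= 3.5 * max(s, 1e-3)
      if (identical(keepNew, keep)) break
      keep <- keepNew
      beta <- irls(muf[keep], vf[keep])
    }
    coefs <- c(b0 = beta[1], b1 = beta[2])
  } else {
    localFit <- stats::loess(log(vf) ~ log(muf), span = 0.4,
                             control = stats::loess.control(surface = "direct"))
  }
  new("DispersionFit", method = method, xi = xi, coefs = coefs,
      localFit = localFit, baseMean = mu, baseVar = v)
}

#' @rdname fittedVariance
setMethod("fittedVariance", "DispersionFit", function(object, mu) {
  raw <- if (object@method == "parametric")
    object@coefs[1] * mu + object@coefs[2] * mu^2
  else
    exp(stats::predict(object@localFit, data.frame(muf = mu)))
  raw[is.na(raw)] <- mu[is.na(raw)]
  unname(pmax(raw, mu * (1 + 1e-8)))
})

#' @rdname fittedDispersion
setMethod("fittedDispersion", "DispersionFit", function(object, mu) {
  v <- fittedVariance(object, mu)
  out <- (v - object@xi * mu) / mu^2
  out[!is.finite(out)] <- 0
  unname(pmax(out, 0))
})

#' Exact negative binomial test for a single-replicate pair
#'
#' Conditions on the total kA + kB: the p-value is the probability, over
#' all splits (a, b) of the total, of splits no more likely than the
#' observed one,
#' \deqn{p = \sum_{a+b=k_A+k_B} P(a)P(b)\,
#'       1[P(a)P(b) \le P(k_A)P(k_B)] / \sum_{a+b=k_A+k_B} P(a)P(b),}
#' where P() are negative binomial densities with means sizeFactor * q
#' (q the pooled normalised mean) and the fitted blind dispersion at q.
#' The split probabilities are enumerated exactly for totals up to 10,000;
#' beyond that the enumeration window is pruned where the excluded density
#' mass is below 1e-12.  A total of zero returns p = 1 by convention.
#'
#' @param kA,kB observed counts (non-negative integers).
#' @param factorA,factorB the two samples' size factors.
#' @param fit a \linkS4class{DispersionFit}.
#' @return the two-sided exact p-value in (0, 1].
#' @export
nbExactTest <- function(kA, kB, factorA, factorB, fit) {
  stopifnot(kA >= 0, kB >= 0)
  S <- kA + kB
  if (S == 0L) return(1)
  q <- (kA / factorA + kB / factorB) / 2
  alpha <- fittedDispersion(fit, q)
  muA <- factorA * q
  muB <- factorB * q
  dens <- function(x, mu) {
    if (alpha > 0) stats::dnbinom(x, mu = mu, size = 1 / alpha)
    else stats::dpois(x, mu)
  }
  if (S <= 10000) {
    a <- 0:S
  } else {
    qlo <- function(mu) {
      if (alpha > 0) stats::qnbinom(1e-14, mu = mu, size = 1 / alpha)
      else stats::qpois(1e-14, mu)
    }
    qhi <- function(mu) {
      if (alpha > 0)
        stats::qnbinom(1e-14, mu = mu, size = 1 / alpha, lower.tail = FALSE)
      else stats::qpois(1e-14, mu, lower.tail = FALSE)
    }
    lo <- max(0, min(qlo(muA), S - qhi(muB), kA))
    hi <- min(S, max(qhi(muA), S - qlo(muB), kA))
    a <- lo:hi
  }
  prod <- dens(a, muA) * dens(S - a, muB)
  obs <- dens(kA, muA) * dens(kB, muB)
  denom <- sum(prod)
  if (denom <= 0) return(1)
  p <- sum(prod[prod <= obs * (1 + 1e-7)]) / denom
  min(max(p, .Machine$double.xmin), 1)
}

#' Call differential expression between two conditions of one subset
#'
#' Runs the exact blind negative binomial test gene by gene between the
#' steady and stimulated sample of one subset.  Size factors and the blind
#' dispersion fit are computed from \emph{all} samples of the experiment
#' (that is the point of the blind method) unless supplied.  Genes with
#' zero counts in every sample of the experiment are excluded as untestable.
#'
#' Thresholds are inclusive: a gene is called at p <= alpha, combined with
#' the fold-change rule of the \linkS4class{DEConfig} (fc >= minFoldChange
#' for up, fc <= 1/minFoldChange for down).  BH-adjusted p-values are always
#' computed and are used for calling when \code{useAdjusted}.  Fold changes
#' are stimulated/steady on normalised counts; when either mean is zero, a
#' half-pseudocount of the smallest positive normalised count is added to
#' both.
#'
#' @param x \code{SummarizedExperiment} with colData columns subset and
#'   condition ("steady"/"stimulated"), or a 2-column count matrix in
#'   (steady, stimulated) order.
#' @param subset which subset to test (ignored for a 2-column matrix).
#' @param config a \linkS4class{DEConfig}.
#' @param factors,fit optional precomputed size factors and blind fit.
#' @return a \linkS4class{DEResult}.
#' @export
callDE <- function(x, subset = NULL, config = deConfig(),
                   factors = NULL, fit = NULL) {
  validObject(config)
  counts <- .countsMatrix(x)
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(cd$subset) || is.null(cd$condition))
      stop("colData must contain 'subset' and 'condition'")
    if (is.null(subset)) stop("specify which subset to test")
    iA <- which(cd$subset == subset & cd$condition == "steady")
    iB <- which(cd$subset == subset & cd$condition == "stimulated")
    if (length(iA) != 1L || length(iB) != 1L)
      stop("subset '", subset,
           "' must have exactly one steady and one stimulated sample")
  } else {
    if (ncol(counts) != 2L)
      stop("a plain matrix must have exactly 2 columns (steady, stimulated)")
    iA <- 1L; iB <- 2L
  }
  if (is.null(factors)) factors <- medianRatioSizeFactors(counts)
  if (is.null(fit)) fit <- fitBlindDispersion(counts, factors)
  testable <- rowSums(counts) > 0
  k <- counts[testable, , drop = FALSE]
  kA <- k[, iA]; kB <- k[, iB]
  sA <- factors[iA]; sB <- factors[iB]
  p <- vapply(seq_along(kA), function(i)
    nbExactTest(kA[i], kB[i], sA, sB, fit), numeric(1))
  meanA <- kA / sA
  meanB <- kB / sB
  pos <- c(meanA[meanA > 0], meanB[meanB > 0])
  cmin <- if (length(pos)) min(pos) else 1
  zero <- meanA == 0 | meanB == 0
  fc <- ifelse(zero, (meanB + 0.5 * cmin) / (meanA + 0.5 * cmin),
               meanB / meanA)
  pAdj <- stats::p.adjust(p, method = "BH")
  pCall <- if (config@useAdjusted) pAdj else p
  call <- ifelse(pCall <= config@alpha & fc >= config@minFoldChange, "up",
          ifelse(pCall <= config@alpha & fc <= 1 / config@minFoldChange,
                 "down", "ns"))
  out <- new("DEResult", S4Vectors::DataFrame(
    gene = rownames(k), meanA = unname(meanA), meanB = unname(meanB),
    fc = unname(fc), log2fc = unname(log2(fc)), pRaw = unname(p),
    pAdj = unname(pAdj), call = unname(call), row.names = rownames(k)))
  S4Vectors::metadata(out) <- list(config = config, subset = subset,
                                   factors = factors,
                                   nUntestable = sum(!testable))
  out
}

#' Genes called differentially expressed
#' @param de a \linkS4class{DEResult}.
#' @param direction "any", "up" or "down".
#' @return character vector of gene symbols.
#' @export
deGenes <- function(de, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") de$call != "ns" else de$call == direction
  de$gene[keep]
}

#' Normalised counts per million
#'
#' Counts are divided by their sample's size factor and each column is then
#' scaled to sum to one million.
#'
#' @param x count matrix or \code{SummarizedExperiment}.
#' @param factors size factors; computed if missing.
#' @return matrix of CPM values, columns summing to 1e6.
#' @export
countsPerMillion <- function(x, factors = NULL) {
  counts <- .countsMatrix(x)
  if (is.null(factors)) factors <- medianRatioSizeFactors(counts)
  nc <- sweep(counts, 2L, factors, "/")
  sweep(nc, 2L, colSums(nc), "/") * 1e6
}
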