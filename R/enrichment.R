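## Over-representation analysis with length-bias correction: a monotone
## length-to-weight function fitted from the DE status, the Wallenius
## noncentral hypergeometric tail (exact recursion for small universes,
## mode-split log-space quadrature otherwise), the odds-ratio statistic,
## term-size filtering with BH adjustment, and the hypergeometric
## gene-list overlap test.

#' Fit a monotone gene length to selection weight function
#'
#' Genes are binned by length into equal-count bins, the per-bin DE
#' proportion is shrunk toward the global DE rate (prior weight: twice the
#' bin size -- a stabiliser against binomial noise in bins), and isotonic
#' regression (pool-adjacent-violators) enforces a non-decreasing step
#' function of length.  Weights are rescaled to mean 1 over the universe
#' and floored at a small positive value.
#'
#' @param de logical vector: is each gene DE?
#' @param lengths numeric vector of gene lengths (same order).
#' @param nbins number of length bins (default 40).
#' @return a list with \code{fun} (vectorised length -> weight),
#'   \code{weights} (per input gene) and the bin table; class
#'   \code{"lengthWeights"}.
#' @export
fitLengthWeights <- function(de, lengths, nbins = 40L) {
  de <- as.logical(de)
  stopifnot(length(de) == length(lengths))
  if (length(de) < 50L) stop("need at least 50 genes to fit the weighting")
  if (all(de) || all(!de))
    stop("need both DE and non-DE genes to fit the weighting")
  ord <- order(lengths)
  n <- length(de)
  nbins <- min(nbins, floor(n / 5))
  bin <- ceiling(seq_along(ord) / (n / nbins))
  bin <- pmin(bin, nbins)
  deo <- de[ord]; leno <- lengths[ord]
  nb <- tabulate(bin, nbins)
  kb <- vapply(seq_len(nbins), function(b) sum(deo[bin == b]), 0)
  pbar <- mean(de)
  prior <- 2 * nb                             # shrinkage prior weight
  prop <- (kb + prior * pbar) / (nb + prior)
  xb <- vapply(seq_len(nbins), function(b) stats::median(leno[bin == b]), 0)
  iso <- stats::isoreg(xb, prop)   # xb is ascending, so yf is in bin order
  yfit <- iso$yf
  stepFun <- stats::approxfun(xb, yfit, method = "constant", rule = 2,
                              f = 0, ties = "ordered")
  raw <- pmax(stepFun(lengths), 1e-6)
  scale <- mean(raw)
  fun <- function(l) pmax(stepFun(l), 1e-6) / scale
  structure(list(fun = fun, weights = raw / scale,
                 bins = data.frame(length = xb, n = nb, de = kb,
                                   prop = prop, fitted = yfit)),
            class = "lengthWeights")
}

## ---------------------------------------------------------------------------
## Wallenius noncentral hypergeometric
## ---------------------------------------------------------------------------

## exact forward recursion over sequential weighted draws; O(n * m1)
.walleniusExact <- function(m1, m2, n, w) {
  f <- numeric(min(n, m1) + 1L)
  f[1] <- 1
  xmaxPrev <- 0L
  for (j in seq_len(n)) {
    xmax <- min(j, m1)
    g <- numeric(length(f))
    for (x in 0:xmaxPrev) {
      if (f[x + 1L] == 0) next
      denom <- w * (m1 - x) + (m2 - (j - 1L - x))
      pw <- if (m1 - x > 0) w * (m1 - x) / denom else 0
      if (pw > 0 && x + 1L <= xmax)
        g[x + 2L] <- g[x + 2L] + f[x + 1L] * pw
      if ((m2 - (j - 1L - x)) > 0)
        g[x + 1L] <- g[x + 1L] + f[x + 1L] * (1 - pw)
    }
    f <- g
    xmaxPrev <- xmax
  }
  f  # f[x+1] = P(X = x)
}

## log pmf by quadrature of the product-integral representation.  The
## integration variable is substituted t = u^D, giving the well-scaled
## beta-like integrand D u^(D-1) (1-u^w)^x (1-u)^(n-x); the naive t-space
## integrand underflows as soon as D is large.  The integral is split at
## the integrand mode (the peak is sharp for large n or D).
.walleniusLogPmfQuad <- function(x, m1, m2, n, w) {
  D <- w * (m1 - x) + (m2 - (n - x))
  if (D <= 0) return(-Inf)
  lc <- lchoose(m1, x) + lchoose(m2, n - x)
  h <- function(u) {
    out <- rep(-Inf, length(u))
    inside <- u > 0 & u < 1
    ui <- u[inside]
    a <- if (x > 0) x * log1p(-ui^w) else 0
    b <- if (n - x > 0) (n - x) * log1p(-ui) else 0
    out[inside] <- (D - 1) * log(ui) + a + b
    out
  }
  opt <- stats::optimize(h, c(1e-12, 1 - 1e-12), maximum = TRUE, tol = 1e-12)
  um <- opt$maximum
  hm <- max(opt$objective, h(c(1e-6, 0.5, 1 - 1e-6)))
  f <- function(u) exp(h(u) - hm)
  I1 <- stats::integrate(f, 0, um, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 500L, stop.on.error = FALSE)
  I2 <- stats::integrate(f, um, 1, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 500L, stop.on.error = FALSE)
  I <- I1$value + I2$value
  if (!is.finite(I) || I <= 0) return(-Inf)
  lc + log(D) + hm + log(I)
}

#' Wallenius noncentral hypergeometric probability mass
#'
#' X is the number of "white" items among n sequential draws without
#' replacement from m1 white and m2 other items, where whites are w times
#' as likely to be taken at every draw.  Exact recursion is used for
#' universes of at most 200 items, log-space quadrature of the standard
#' product-integral representation (split at the integrand mode) otherwise.
#' The mass function is renormalised over its support.
#'
#' @param x quantile(s).
#' @param m1,m2 white and non-white item counts.
#' @param n number of draws.
#' @param w odds of a white item.
#' @return P(X = x).
#' @export
dWallenius <- function(x, m1, m2, n, w) {
  stopifnot(n <= m1 + m2, w > 0)
  support <- max(0L, n - m2):min(n, m1)
  pmf <- if (m1 + m2 <= 200L) {
    f <- .walleniusExact(m1, m2, n, w)
    f[support + 1L]
  } else {
    lp <- vapply(support, .walleniusLogPmfQuad, numeric(1),
                 m1 = m1, m2 = m2, n = n, w = w)
    exp(lp - max(lp))
  }
  pmf <- pmf / sum(pmf)
  out <- numeric(length(x))
  ok <- x %in% support
  out[ok] <- pmf[match(x[ok], support)]
  out
}

#' Wallenius noncentral hypergeometric upper tail
#'
#' @inheritParams dWallenius
#' @param q quantile; returns P(X >= q).
#' @return upper-tail probability in (0, 1].
#' @export
pWalleniusUpper <- function(q, m1, m2, n, w) {
  support <- max(0L, n - m2):min(n, m1)
  pmf <- dWallenius(support, m1, m2, n, w)
  p <- sum(pmf[support >= q])
  min(max(p, .Machine$double.xmin), 1)
}

#' Length-bias-corrected over-representation of one term
#'
#' Builds the 2x2 table of DE status by term membership over the universe,
#' computes the odds ratio as the odds of a DE gene occurring in the term
#' divided by the odds of a non-DE gene occurring in the term, and the
#' upper-tail p-value under the Wallenius noncentral hypergeometric law
#' with odds w = (mean selection weight inside the term) / (mean weight
#' outside), which reduces to the central hypergeometric when all weights
#' are equal.  Degenerate tables (an empty row or column) give p = 1 and an
#' NA odds ratio.
#'
#' @param deSet character vector of DE genes.
#' @param term character vector of term members.
#' @param universe character vector of all testable genes.
#' @param weights per-gene selection weights, named by gene (default all 1).
#' @return one-row data.frame with the table cells, oddsRatio, odds w and
#'   pRaw.
#' @export
walleniusORA <- function(deSet, term, universe, weights = NULL) {
  universe <- unique(universe)
  N <- length(universe)
  if (is.null(weights)) weights <- stats::setNames(rep(1, N), universe)
  term <- intersect(term, universe)
  if (!length(term)) stop("term has no overlap with the universe")
  deSet <- intersect(deSet, universe)
  inTerm <- universe %in% term
  isDE <- universe %in% deSet
  a <- sum(isDE & inTerm)      # DE in term
  b <- sum(isDE & !inTerm)     # DE out
  cc <- sum(!isDE & inTerm)    # non-DE in term
  d <- sum(!isDE & !inTerm)    # non-DE out
  degenerate <- (a + b) == 0L || (cc + d) == 0L ||
    (a + cc) == 0L || (b + d) == 0L
  oddsRatio <- if (degenerate) NA_real_ else (a / b) / (cc / d)
  if (degenerate) {
    p <- 1; w <- NA_real_
  } else {
    wIn <- mean(weights[universe[inTerm]])
    wOut <- mean(weights[universe[!inTerm]])
    w <- wIn / wOut
    if (!is.finite(w) || w <= 0) w <- 1
    p <- pWalleniusUpper(a, m1 = length(term), m2 = N - length(term),
                         n = length(deSet), w = w)
  }
  data.frame(nDEIn = a, nDEOut = b, nNonDEIn = cc, nNonDEOut = d,
             oddsRatio = oddsRatio, odds = w, pRaw = p)
}

#' Run over-representation analysis for two subsets side by side
#'
#' Terms are intersected with the universe; terms in which fewer than
#' \code{minObserved} genes are observed in \emph{both} subsets are removed
#' before testing (observation in one subset suffices to retain a term).
#' "Observed" genes of a subset are that subset's DE genes in the term.
#' BH adjustment is applied within each subset's family of retained terms,
#' separately per annotation source.
#'
#' @param deSets named list of two character vectors of DE genes
#'   (subsets A and B).
#' @param annotations named list of term member vectors, or the list
#'   returned by [genAnnotations()] / with an \code{info} data.frame
#'   carrying a \code{source} column.
#' @param universe all testable genes.
#' @param weights list of two per-gene weight vectors (or a single vector
#'   used for both subsets; NULL for unweighted).
#' @param minObserved minimum observed genes per term (default 10).
#' @param alpha significance threshold on adjusted p-values (inclusive).
#' @return data.frame, one row per retained term, with per-subset observed
#'   counts, odds ratios, raw and adjusted p-values and significance flags.
#' @export
runORA <- function(deSets, annotations, universe, weights = NULL,
                   minObserved = 10L, alpha = 0.05) {
  if (is.list(annotations) && !is.null(annotations$sets)) {
    info <- annotations$info
    sets <- annotations$sets
  } else {
    sets <- annotations
    if (!length(sets)) stop("empty annotation set list")
    info <- data.frame(term = names(sets), source = "annotation")
  }
  if (!length(sets)) stop("empty annotation set list")
  stopifnot(length(deSets) == 2L)
  if (is.null(names(deSets))) names(deSets) <- c("A", "B")
  universe <- unique(universe)
  sets <- lapply(sets, intersect, universe)
  keepNE <- lengths(sets) > 0L
  sets <- sets[keepNE]
  info <- info[match(names(sets), info$term), , drop = FALSE]
  if (is.null(weights)) weights <- list(NULL, NULL)
  if (!is.list(weights)) weights <- list(weights, weights)
  obs <- vapply(sets, function(tm)
    c(length(intersect(deSets[[1]], tm)), length(intersect(deSets[[2]], tm))),
    numeric(2))
  keep <- !(obs[1, ] < minObserved & obs[2, ] < minObserved)
  sets <- sets[keep]
  info <- info[keep, , drop = FALSE]
  if (!length(sets)) {
    return(data.frame(term = character(), source = character()))
  }
  resFor <- function(s) {
    rows <- lapply(sets, function(tm)
      walleniusORA(deSets[[s]], tm, universe, weights[[s]]))
    do.call(rbind, rows)
  }
  rA <- resFor(1L); rB <- resFor(2L)
  adjBy <- function(p, src) {
    out <- numeric(length(p))
    for (g in unique(src)) {
      i <- src == g
      out[i] <- stats::p.adjust(p[i], method = "BH")
    }
    out
  }
  src <- if (!is.null(info$source)) info$source else rep("annotation",
                                                         length(sets))
  out <- data.frame(term = names(sets), source = src,
                    nObsA = rA$nDEIn, oddsRatioA = rA$oddsRatio,
                    pRawA = rA$pRaw, pAdjA = adjBy(rA$pRaw, src),
                    nObsB = rB$nDEIn, oddsRatioB = rB$oddsRatio,
                    pRawB = rB$pRaw, pAdjB = adjBy(rB$pRaw, src),
                    row.names = NULL)
  out$sigA <- out$pAdjA <= alpha
  out$sigB <- out$pAdjB <= alpha
  out
}

#' Hypergeometric gene-list overlap test
#'
#' Significance of the overlap k between two gene lists drawn from a common
#' universe of size N: p = P(X >= k) with
#' X ~ Hypergeometric(N, |A|, |B|).  The inverse p-value (for display on a
#' log scale) is included.
#'
#' @param listA,listB character vectors, both subsets of \code{universe}.
#' @param universe the common gene universe.
#' @return list with N, nA, nB, k, p and invP.
#' @examples
#' overlapTest(letters[1:3], letters[1:3], letters[1:10])$p  # 1/choose(10,3)
#' @export
overlapTest <- function(listA, listB, universe) {
  universe <- unique(universe)
  listA <- unique(listA); listB <- unique(listB)
  offA <- setdiff(listA, universe); offB <- setdiff(listB, universe)
  if (length(offA) || length(offB))
    stop("lists are not subsets of the universe; offenders: ",
         paste(utils::head(c(offA, offB), 10), collapse = ", "))
  N <- length(universe)
  nA <- length(listA); nB <- length(listB)
  k <- length(intersect(listA, listB))
  p <- stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(N = N, nA = nA, nB = nB, k = k, p = p, invP = 1 / p)
}
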