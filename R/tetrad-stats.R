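# Tetrad viability summaries and the exact tests applied to dissection data.

#' Summarize spore viability from tetrad records
#'
#' @param tetrads Tetrad records (one row per spore; see
#'   \code{\link{simulateMeiosisTetrads}} and \code{\link{readTetradTable}}).
#' @param loci Genotype columns to summarize per-genotype viability for;
#'   defaults to every column beyond the bookkeeping ones.
#' @return List with \code{viable}, \code{total}, \code{fraction},
#'   \code{perGenotype} (data.frame: locus, allele, viable, total, fraction,
#'   over genotyped spores), and \code{histogram} (named count vector of
#'   viable spores per tetrad, 0..4).
#' @export
summarizeViability <- function(tetrads, loci = NULL) {
  stopifnot(nrow(tetrads) >= 1)
  if (is.null(loci))
    loci <- setdiff(names(tetrads),
                    c("crossId", "tetradId", "sporeIndex", "viable"))
  viable <- as.logical(tetrads$viable)
  perTetrad <- tapply(viable, interaction(tetrads$crossId, tetrads$tetradId,
                                          drop = TRUE), sum)
  hist <- table(factor(perTetrad, levels = 0:4))
  pg <- list()
  for (loc in loci) {
    g <- tetrads[[loc]]
    for (al in sort(unique(stats::na.omit(g)))) {
      sel <- !is.na(g) & g == al
      pg[[length(pg) + 1L]] <- data.frame(
        locus = loc, allele = al, viable = sum(viable[sel]),
        total = sum(sel), fraction = mean(viable[sel]))
    }
  }
  list(viable = sum(viable), total = length(viable),
       fraction = mean(viable),
       perGenotype = if (length(pg)) do.call(rbind, pg) else NULL,
       histogram = hist)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Exact two-sided p-value by the method of small p-values: the sum of
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' relative tie tolerance of 1e-7).
#'
#' @param a,b,c,d Cell counts of the 2x2 table (rows: group; columns:
#'   outcome).
#' @return Two-sided p-value in \code{(0, 1]}.
#' @examples
#' fisherExact2x2(10, 0, 0, 10)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    warnf("degenerate margin in 2x2 table; p = 1")
    return(1)
  }
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  pObs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  min(p, 1)
}

#' Exact binomial goodness-of-fit test (two-sided)
#'
#' Two-sided p-value by the method of small p-values: the sum of
#' Binomial(n, p0) probabilities over all outcomes whose probability does not
#' exceed that of the observed count (within a relative tie tolerance of
#' 1e-7).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return Two-sided p-value in \code{(0, 1]}.
#' @examples
#' exactBinomialTwoSided(0, 10)   # 2 * 0.5^10
#' exactBinomialTwoSided(1, 10)   # 22/1024
#' @export
exactBinomialTwoSided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  probs <- dbinom(0:n, n, p0)
  pObs <- probs[k + 1L]
  min(sum(probs[probs <= pObs * (1 + 1e-7)]), 1)
}

# Infer missing genotypes of dead spores from tetrad mates: each locus
# segregates 2:2 within a tetrad, so when three spores are typed (two of one
# allele, one of the other) the fourth spore's allele is determined.
.completeTetradGenotypes <- function(tetrads, locus) {
  g <- tetrads[[locus]]
  inferred <- logical(length(g))
  for (tid in unique(tetrads$tetradId)) {
    ix <- which(tetrads$tetradId == tid)
    if (length(ix) != 4L) next
    known <- g[ix]
    miss <- is.na(known)
    if (sum(miss) != 1L) next
    cnt <- table(known[!miss])
    if (length(cnt) == 2L && all(sort(as.integer(cnt)) == c(1L, 2L))) {
      g[ix][miss] <- names(cnt)[which.min(cnt)]
      inferred[ix][miss] <- TRUE
    }
  }
  list(genotype = g, inferred = inferred)
}

#' Test a genotype ratio against 1:1 segregation
#'
#' Counts spores carrying the focal allele among genotyped spores of the
#' selected viability class and tests the count against the Mendelian 50%
#' expectation with the exact binomial test.
#'
#' @param tetrads Tetrad records.
#' @param locus Genotype column to test.
#' @param allele Focal allele; defaults to the lexicographically first allele
#'   observed at the locus.
#' @param among Which spores to count: \code{"viable"} (default; dead spores
#'   typically cannot be genotyped), \code{"dead"}, or \code{"all"}.
#' @param inferDead If TRUE, genotypes of untyped dead spores are completed
#'   from their tetrad mates using 2:2 segregation where determined; the
#'   result is flagged.
#' @return List with \code{k}, \code{n}, \code{pValue}, \code{allele},
#'   \code{inferenceUsed}.
#' @export
genotypeRatioTest <- function(tetrads, locus, allele = NULL,
                              among = c("viable", "dead", "all"),
                              inferDead = FALSE) {
  among <- match.arg(among)
  if (!locus %in% names(tetrads)) stopf("no genotype column '%s'", locus)
  g <- tetrads[[locus]]
  inferenceUsed <- FALSE
  if (inferDead) {
    comp <- .completeTetradGenotypes(tetrads, locus)
    inferenceUsed <- any(comp$inferred)
    g <- comp$genotype
  }
  viable <- as.logical(tetrads$viable)
  sel <- switch(among, viable = viable, dead = !viable,
                all = rep(TRUE, length(viable)))
  sel <- sel & !is.na(g)
  if (!sum(sel)) stopf("no genotyped spores in class '%s'", among)
  if (is.null(allele)) allele <- sort(unique(g[sel]))[1]
  k <- sum(g[sel] == allele)
  n <- sum(sel)
  list(k = k, n = n, pValue = exactBinomialTwoSided(k, n, 0.5),
       allele = allele, inferenceUsed = inferenceUsed)
}
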