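# Analytic poison-antidote model: spore survival, exact tetrad expectations,
# and maximum-likelihood fitting of killer parameters.

#' Survival probability of a single spore
#'
#' Under the poison-antidote model every killer present in the parental
#' diploid poisons all four spores of the ascus. A spore survives killer k
#' with probability \code{1 - kappa_k * (1 - prot_k)}, where \code{prot_k} is
#' the best antidote efficiency among alleles the spore carries whose
#' resistance set contains k (0 if it carries none). Killers act
#' independently, so the survival probability is the product over killers.
#' A spore inheriting one of two mutually non-resistant killers is therefore
#' still killed by the other.
#'
#' @param genotype Named character vector mapping locus id to the allele the
#'   spore carries.
#' @param killers List of \linkS4class{KillerAllele} present in the parental
#'   diploid.
#' @return Survival probability in \code{[0, 1]}.
#' @examples
#' k <- killerAllele("cw9", "L1")
#' sporeSurvivalProbability(c(L1 = "cw9"), list(k))  # 1: self-protected
#' sporeSurvivalProbability(c(L1 = "+"), list(k))    # 0: poisoned, no antidote
#' @export
sporeSurvivalProbability <- function(genotype, killers) {
  carried <- unname(genotype)
  s <- 1
  for (k in killers) {
    if (!k@locus %in% names(genotype))
      stopf("genotype is missing killer locus '%s'", k@locus)
    prot <- 0
    for (a in killers) {
      if (a@id %in% carried && k@id %in% a@resistanceSet)
        prot <- max(prot, a@pi)
    }
    s <- s * (1 - k@kappa * (1 - prot))
  }
  s
}

# --- exact enumeration of tetrad segregation patterns ---------------------

# All origin vectors (4 spores, values 1/2) with 2:2 segregation
.originStates <- local({
  m <- t(utils::combn(4, 2))
  lapply(seq_len(nrow(m)), function(i) {
    o <- rep(2L, 4); o[m[i, ]] <- 1L; o
  })
})

# Enumerate joint parent-of-origin patterns for the loci of one chromosome.
# Returns list of list(mat = 4 x L origin matrix, prob). The first locus takes
# each 2:2 arrangement with probability 1/6; each following interval either
# keeps the arrangement (prob 1 - 2r) or exchanges the origins of one
# currently-parent1 spore and one currently-parent2 spore (prob r/2 per
# choice), which preserves 2:2 at every locus and gives each spore a marginal
# recombination probability r.
.enumChromosome <- function(rFractions) {
  L <- length(rFractions) + 1L
  states <- lapply(.originStates, function(o)
    list(mat = matrix(o, nrow = 4, ncol = 1), prob = 1 / 6))
  for (r in rFractions) {
    out <- list()
    for (st in states) {
      cur <- st$mat[, ncol(st$mat)]
      if (1 - 2 * r > 0) {
        out[[length(out) + 1L]] <-
          list(mat = cbind(st$mat, cur), prob = st$prob * (1 - 2 * r))
      }
      if (r > 0) {
        i1 <- which(cur == 1L); i2 <- which(cur == 2L)
        for (i in i1) for (j in i2) {
          nxt <- cur; nxt[i] <- 2L; nxt[j] <- 1L
          out[[length(out) + 1L]] <-
            list(mat = cbind(st$mat, nxt), prob = st$prob * r / 2)
        }
      }
    }
    # merge identical patterns to keep the state space small
    keys <- vapply(out, function(s) paste(s$mat, collapse = ""), "")
    states <- lapply(split(seq_along(out), keys), function(ix) {
      list(mat = out[[ix[1]]]$mat,
           prob = sum(vapply(out[ix], `[[`, 0, "prob")))
    })
  }
  states
}

# Joint enumeration across chromosomes -> list of (4 x nLoci origin matrix,
# prob), columns ordered as config loci.
.enumTetradPatterns <- function(config, maxStates = 2e5) {
  lo <- lociTable(config)
  chroms <- unique(lo$chromosome)
  perChrom <- lapply(chroms, function(chr) {
    sub <- lo[lo$chromosome == chr, , drop = FALSE]
    r <- sub$recombFractionToNext[-nrow(sub)]
    if (nrow(sub) == 1L) r <- numeric()
    .enumChromosome(r)
  })
  total <- prod(vapply(perChrom, length, 0L))
  if (total > maxStates)
    stopf("tetrad enumeration would need %d states; too many loci", total)
  joint <- list(list(mat = matrix(integer(), nrow = 4, ncol = 0), prob = 1))
  for (cs in perChrom) {
    joint <- unlist(lapply(joint, function(j) {
      lapply(cs, function(s)
        list(mat = cbind(j$mat, s$mat), prob = j$prob * s$prob))
    }), recursive = FALSE)
  }
  # column order: chromosomes were taken in loci-table order, so columns
  # already match lociTable(config) rows
  joint
}

# Genotypes (named character per spore) for one origin matrix
.patternGenotypes <- function(config, mat) {
  lo <- lociTable(config)
  ids <- lo$id
  lapply(1:4, function(s) {
    o <- mat[s, ]
    setNames(ifelse(o == 1L, config@parent1[ids], config@parent2[ids]), ids)
  })
}

#' Exact distribution of viable spores per tetrad
#'
#' Enumerates all tetrad segregation patterns of the cross (2:2 segregation of
#' every locus within a tetrad, per-interval recombination arrangements
#' weighted by the recombination fractions, independent assortment across
#' chromosomes), applies per-spore survival probabilities, and returns the
#' exact distribution of the number of viable spores per tetrad.
#'
#' @param config A \linkS4class{CrossConfig}.
#' @return Named numeric vector of probabilities for 0..4 viable spores
#'   (sums to 1).
#' @examples
#' cfg <- crossConfig(
#'   loci = data.frame(id = "k", chromosome = "III", position = 1e6),
#'   parent1 = c(k = "cw9"), parent2 = c(k = "+"),
#'   killers = list(killerAllele("cw9", "k")))
#' tetradOutcomeDistribution(cfg)  # all mass on 2 viable: the 2:2 pattern
#' @export
tetradOutcomeDistribution <- function(config) {
  killers <- activeKillers(config)
  dist <- setNames(numeric(5), 0:4)
  for (st in .enumTetradPatterns(config)) {
    gs <- .patternGenotypes(config, st$mat)
    s <- vapply(gs, sporeSurvivalProbability, 0, killers = killers)
    # Poisson-binomial over the four spores by convolution
    pv <- 1
    for (si in s) pv <- c(pv * (1 - si), 0) + c(0, pv * si)
    dist <- dist + st$prob * pv
  }
  dist
}

#' Expected fraction of viable spores
#'
#' @param config A \linkS4class{CrossConfig}.
#' @return Expected viable fraction in \code{[0, 1]} (mean of the tetrad
#'   outcome distribution divided by 4).
#' @examples
#' # a single heterozygous fully penetrant killer halves spore viability
#' @export
expectedViability <- function(config) {
  d <- tetradOutcomeDistribution(config)
  sum(d * 0:4) / 4
}

#' Expected allele frequency among viable spores
#'
#' Computes, by exact enumeration, the expected frequency of an allele in a
#' large pool of surviving spores: the ratio of the expected number of viable
#' allele-carrying spores to the expected number of viable spores.
#'
#' @param config A \linkS4class{CrossConfig}.
#' @param locus Locus id.
#' @param allele Allele label whose pooled frequency is wanted.
#' @return Frequency in \code{[0, 1]}.
#' @examples
#' # at a fully penetrant killer locus the non-killer allele frequency is 0
#' @export
expectedViableAlleleFrequency <- function(config, locus, allele) {
  lo <- lociTable(config)
  if (!locus %in% lo$id) stopf("locus '%s' not in config", locus)
  killers <- activeKillers(config)
  num <- 0; den <- 0
  for (st in .enumTetradPatterns(config)) {
    gs <- .patternGenotypes(config, st$mat)
    s <- vapply(gs, sporeSurvivalProbability, 0, killers = killers)
    carry <- vapply(gs, function(g) g[[locus]] == allele, NA)
    num <- num + st$prob * sum(s[carry])
    den <- den + st$prob * sum(s)
  }
  if (den <= 0) stopf("no viable spores under this configuration")
  num / den
}

# --- maximum-likelihood fitting ------------------------------------------

# survival probabilities for each genotype pattern (rows of `carryMat`,
# logical: does the pattern carry allele j) for one parameter vector
.patternSurvival <- function(carryMat, killers, kappa, pi) {
  s <- rep(1, nrow(carryMat))
  for (ki in seq_along(killers)) {
    k <- killers[[ki]]
    prot <- rep(0, nrow(carryMat))
    for (ai in seq_along(killers)) {
      a <- killers[[ai]]
      if (k@id %in% a@resistanceSet)
        prot <- pmax(prot, ifelse(carryMat[, ai], pi[ai], 0))
    }
    s <- s * (1 - kappa[ki] * (1 - prot))
  }
  s
}

#' Fit killer parameters by maximum likelihood
#'
#' Estimates killing penetrance (kappa) and antidote efficiency (pi) for each
#' killer in a given model structure from tetrad dissection records, by
#' maximizing the Bernoulli likelihood of per-spore viability under the
#' survival model of \code{\link{sporeSurvivalProbability}}. Optimization is
#' deterministic: an exhaustive coarse grid (step 0.05) followed by local
#' refinement with box-constrained BFGS, so repeated fits of the same data
#' give identical results.
#'
#' @param tetrads Tetrad records as returned by
#'   \code{\link{simulateMeiosisTetrads}} (or read with
#'   \code{\link{readTetradTable}}): one row per spore with columns
#'   \code{viable} and one genotype column per locus.
#' @param killers List of \linkS4class{KillerAllele} giving the model
#'   structure (ids, loci, resistance sets); their kappa/pi values are ignored
#'   and re-estimated.
#' @param gridStep Coarse grid spacing in parameter space.
#' @return A list with \code{estimates} (data.frame: id, kappa, pi,
#'   identifiability flags, boundary flags), \code{logLik}, and
#'   \code{convergence} (0 for success, from \code{optim}).
#' @export
fitKillerParameters <- function(tetrads, killers, gridStep = 0.05) {
  loci <- vapply(killers, function(k) k@locus, "")
  ids <- vapply(killers, function(k) k@id, "")
  missingCols <- setdiff(loci, names(tetrads))
  if (length(missingCols))
    stopf("tetrad table lacks genotype column(s): %s",
          paste(missingCols, collapse = ", "))
  geno <- tetrads[, loci, drop = FALSE]
  ok <- stats::complete.cases(geno) & !is.na(tetrads$viable)
  if (!all(ok))
    warnf("dropping %d spore(s) with missing genotype or viability", sum(!ok))
  geno <- geno[ok, , drop = FALSE]
  viable <- as.logical(tetrads$viable[ok])
  if (!nrow(geno)) stopf("no usable spores")

  # collapse to unique carrier patterns
  carry <- vapply(seq_along(killers), function(j) geno[[loci[j]]] == ids[j],
                  logical(nrow(geno)))
  carry <- matrix(carry, ncol = length(killers))
  key <- apply(carry, 1, paste, collapse = "")
  patKeys <- unique(key)
  carryMat <- carry[match(patKeys, key), , drop = FALSE]
  nViable <- vapply(patKeys, function(kk) sum(viable[key == kk]), 0)
  nDead <- vapply(patKeys, function(kk) sum(!viable[key == kk]), 0)

  eps <- 1e-12
  negll <- function(par) {
    K <- length(killers)
    kap <- pmin(pmax(par[seq_len(K)], 0), 1)
    pii <- pmin(pmax(par[K + seq_len(K)], 0), 1)
    s <- .patternSurvival(carryMat, killers, kap, pii)
    -sum(nViable * log(pmax(s, eps)) + nDead * log(pmax(1 - s, eps)))
  }

  K <- length(killers)
  gridVals <- seq(0, 1, by = gridStep)
  gridList <- rep(list(gridVals), 2 * K)
  grid <- as.matrix(do.call(expand.grid, gridList))
  nll <- apply(grid, 1, negll)
  best <- grid[which.min(nll), ]
  opt <- stats::optim(best, negll, method = "L-BFGS-B",
                      lower = rep(0, 2 * K), upper = rep(1, 2 * K))
  par <- pmin(pmax(opt$par, 0), 1)
  if (opt$value > min(nll) + 1e-9) {  # refinement must not lose ground
    par <- best
    opt$value <- min(nll)
  }

  # identifiability: kappa needs exposed non-protected spores observed;
  # pi needs carrier spores observed
  kapId <- vapply(seq_len(K), function(j) {
    protIdx <- which(vapply(killers, function(a)
      ids[j] %in% a@resistanceSet, NA))
    any(rowSums(carryMat[, protIdx, drop = FALSE]) == 0 &
        (nViable + nDead) > 0)
  }, NA)
  piId <- vapply(seq_len(K), function(j)
    any(carryMat[, j] & (nViable + nDead) > 0), NA)

  est <- data.frame(
    id = ids,
    kappa = par[seq_len(K)],
    pi = par[K + seq_len(K)],
    kappaIdentifiable = kapId,
    piIdentifiable = piId,
    boundary = par[seq_len(K)] %in% c(0, 1) | par[K + seq_len(K)] %in% c(0, 1),
    row.names = NULL)
  list(estimates = est, logLik = -opt$value, convergence = opt$convergence)
}
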