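# Synthetic-data generators for crosses: tetrads, viable-spore pools,
# pooled-sequencing allele-count tables, and mosaic backcross genomes.
# All generators are reproducible bitwise given the same seed.

# sample one tetrad's origin matrix (4 x nLoci) under the model used by the
# exact enumeration: 2:2 at the first locus of each chromosome, and per
# interval either no exchange (prob 1 - 2r) or an exchange of one
# currently-parent1 and one currently-parent2 spore (prob 2r).
.sampleTetradOrigins <- function(lo) {
  mat <- matrix(0L, nrow = 4, ncol = nrow(lo))
  for (chr in unique(lo$chromosome)) {
    idx <- which(lo$chromosome == chr)
    o <- rep(2L, 4); o[sample.int(4, 2)] <- 1L
    mat[, idx[1]] <- o
    if (length(idx) > 1L) {
      for (j in seq_len(length(idx) - 1L)) {
        r <- lo$recombFractionToNext[idx[j]]
        if (stats::runif(1) < 2 * r) {
          i1 <- which(o == 1L); i2 <- which(o == 2L)
          a <- i1[sample.int(2, 1)]; b <- i2[sample.int(2, 1)]
          o[a] <- 2L; o[b] <- 1L
        }
        mat[, idx[j + 1L]] <- o
      }
    }
  }
  mat
}

#' Simulate tetrad dissection data
#'
#' Simulates meioses of a configured cross and the killer-dependent death of
#' spores. Every locus segregates 2:2 within each tetrad; spore death is
#' sampled from the survival probabilities of
#' \code{\link{sporeSurvivalProbability}}.
#'
#' @param config A \linkS4class{CrossConfig}.
#' @param n Number of tetrads.
#' @param seed Integer seed; output is bitwise reproducible.
#' @param crossId Label recorded in the output.
#' @param hideDeadGenotypes If TRUE, genotypes of dead spores are set to NA,
#'   mimicking real dissection data where dead spores cannot be genotyped.
#' @return data.frame with one row per spore: \code{crossId},
#'   \code{tetradId}, \code{sporeIndex}, \code{viable}, and one genotype
#'   column per locus.
#' @examples
#' cfg <- crossConfig(
#'   loci = data.frame(id = "k", chromosome = "III", position = 1e6),
#'   parent1 = c(k = "cw9"), parent2 = c(k = "+"),
#'   killers = list(killerAllele("cw9", "k")))
#' head(simulateMeiosisTetrads(cfg, n = 5, seed = 1))
#' @export
simulateMeiosisTetrads <- function(config, n, seed, crossId = "cross1",
                                   hideDeadGenotypes = FALSE) {
  stopifnot(n >= 1)
  lo <- lociTable(config)
  killers <- activeKillers(config)
  withSeed(seed, {
    rows <- vector("list", n)
    for (t in seq_len(n)) {
      mat <- .sampleTetradOrigins(lo)
      gs <- .patternGenotypes(config, mat)
      s <- vapply(gs, sporeSurvivalProbability, 0, killers = killers)
      viable <- stats::runif(4) < s
      g <- do.call(rbind, lapply(gs, function(x) as.data.frame(as.list(x))))
      if (hideDeadGenotypes) g[!viable, ] <- NA
      rows[[t]] <- cbind(
        data.frame(crossId = crossId, tetradId = t, sporeIndex = 1:4,
                   viable = viable),
        g)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a pool of viable spore colonies
#'
#' Emulates random spore analysis followed by pooling of viable colonies:
#' independent spores are drawn from the cross (each spore's parent-of-origin
#' follows a Markov chain along each chromosome with the configured
#' recombination fractions), kept with probability equal to their survival,
#' and collected until \code{nColonies} are obtained.
#'
#' @param config A \linkS4class{CrossConfig}.
#' @param nColonies Number of viable colonies to collect.
#' @param seed Integer seed.
#' @param maxAttempts Bound on the number of spores sampled before giving up
#'   (guards against configurations with viability 0).
#' @return data.frame of genotypes (one row per colony, one column per
#'   locus), with attributes \code{origins} (matrix of parent-of-origin,
#'   1 = parent1) and \code{loci} (the locus table).
#' @export
simulateViableSporePool <- function(config, nColonies, seed,
                                    maxAttempts = 1000 * nColonies) {
  lo <- lociTable(config)
  killers <- activeKillers(config)
  ids <- lo$id
  withSeed(seed, {
    got <- 0L; attempts <- 0L
    origins <- matrix(0L, nrow = nColonies, ncol = nrow(lo),
                      dimnames = list(NULL, ids))
    while (got < nColonies) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stopf("no viable spores collected after %d attempts; viability may be 0",
              maxAttempts)
      o <- integer(nrow(lo))
      for (chr in unique(lo$chromosome)) {
        idx <- which(lo$chromosome == chr)
        cur <- sample(1:2, 1)
        o[idx[1]] <- cur
        if (length(idx) > 1L) for (j in seq_len(length(idx) - 1L)) {
          r <- lo$recombFractionToNext[idx[j]]
          if (stats::runif(1) < r) cur <- 3L - cur
          o[idx[j + 1L]] <- cur
        }
      }
      g <- setNames(ifelse(o == 1L, config@parent1[ids], config@parent2[ids]),
                    ids)
      if (stats::runif(1) < sporeSurvivalProbability(g, killers)) {
        got <- got + 1L
        origins[got, ] <- o
      }
    }
    geno <- as.data.frame(lapply(setNames(seq_along(ids), ids), function(j)
      ifelse(origins[, j] == 1L, config@parent1[ids[j]], config@parent2[ids[j]])))
    attr(geno, "origins") <- origins
    attr(geno, "loci") <- lo
    geno
  })
}

#' Generate a synthetic SNP map
#'
#' Places segregating SNPs along chromosomes between two parental haplotypes,
#' with the reference allele assigned to parent 1. The default density of 25
#' SNPs per 100 kb echoes, at reduced scale, the multi-SNPs-per-kb divergence
#' between distant fission-yeast isolates.
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param densityPer100kb Expected SNPs per 100 kb.
#' @param seed Integer seed.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{var}; positions strictly increasing per chromosome.
#' @examples
#' head(makeSnpMap(c(III = 1e6), seed = 1))
#' @export
makeSnpMap <- function(chromLengths, densityPer100kb = 25, seed = 1) {
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    out <- lapply(names(chromLengths), function(chr) {
      nSnp <- max(1L, round(chromLengths[[chr]] * densityPer100kb / 1e5))
      pos <- sort(sample.int(chromLengths[[chr]], nSnp))
      ref <- sample(bases, nSnp, replace = TRUE)
      var <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      data.frame(chrom = chr, pos = pos, ref = ref, var = unname(var))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

# Conditional sampling of parent-of-origin at untyped positions given origins
# at typed positions: symmetric two-state Markov bridge with Haldane
# transition probabilities. `positions` sorted; `knownIdx`/`knownOrig`
# (matrix members x typed loci) give the constraints. Returns members x
# positions matrix of origins (1/2).
.bridgeOrigins <- function(positions, knownIdx, knownOrig, nMembers, cMPerKb) {
  nPos <- length(positions)
  out <- matrix(0L, nrow = nMembers, ncol = nPos)
  if (length(knownIdx)) out[, knownIdx] <- knownOrig
  rFlip <- c(haldaneFraction(diff(positions), cMPerKb), 0)
  # distance (bp) from each position to the next typed position
  nextKnown <- rep(NA_integer_, nPos)
  lastSeen <- NA_integer_
  for (i in nPos:1) {
    if (i %in% knownIdx) lastSeen <- i
    nextKnown[i] <- lastSeen
  }
  for (i in seq_len(nPos)) {
    if (i %in% knownIdx) next
    if (i == 1L) {
      # before any typed locus: run the chain backward from the first typed
      # locus, or unconditionally if none
      if (!is.na(nextKnown[1])) {
        r <- haldaneFraction(positions[nextKnown[1]] - positions[1], cMPerKb)
        flip <- stats::runif(nMembers) < r
        out[, 1] <- ifelse(flip, 3L - out[, nextKnown[1]], out[, nextKnown[1]])
      } else {
        out[, 1] <- sample(1:2, nMembers, replace = TRUE)
      }
      next
    }
    r1 <- rFlip[i - 1L]
    nk <- nextKnown[i]
    if (is.na(nk)) {
      flip <- stats::runif(nMembers) < r1
    } else {
      r2 <- haldaneFraction(positions[nk] - positions[i], cMPerKb)
      differs <- out[, i - 1L] != out[, nk]
      pFlip <- ifelse(differs,
                      r1 * (1 - r2) / pmax(r1 * (1 - r2) + (1 - r1) * r2, 1e-300),
                      r1 * r2 / pmax(r1 * r2 + (1 - r1) * (1 - r2), 1e-300))
      flip <- stats::runif(nMembers) < pFlip
    }
    out[, i] <- ifelse(flip, 3L - out[, i - 1L], out[, i - 1L])
  }
  out
}

#' Simulate pooled sequencing read counts over a viable-spore pool
#'
#' Given a pool of viable spores typed at the cross loci, interpolates each
#' member's parent-of-origin at every SNP of the map (Markov bridge between
#' typed loci under the Haldane map function), then draws sequencing depth
#' per SNP from Poisson(\code{meanDepth}) and reference-base counts from a
#' binomial with the pool reference-allele frequency (optionally perturbed by
#' a per-base mis-call rate).
#'
#' @param pool Output of \code{\link{simulateViableSporePool}}.
#' @param snpMap SNP map from \code{\link{makeSnpMap}}.
#' @param meanDepth Mean sequencing depth per SNP.
#' @param seed Integer seed.
#' @param errorRate Per-base probability that a read reports the other
#'   allele; default 0 (base-quality filtering is assumed upstream).
#' @param cMPerKb Recombination rate for the interpolation.
#' @return Allele-count table: data.frame \code{chrom}, \code{pos},
#'   \code{ref}, \code{var}, \code{refCount}, \code{varCount}. Parent 1
#'   carries the reference allele at every SNP.
#' @export
simulatePoolReadcounts <- function(pool, snpMap, meanDepth = 15, seed = 1,
                                   errorRate = 0, cMPerKb = 0.16) {
  origins <- attr(pool, "origins")
  lo <- attr(pool, "loci")
  if (is.null(origins) || is.null(lo))
    stopf("pool must carry 'origins' and 'loci' attributes (see simulateViableSporePool)")
  nMembers <- nrow(origins)
  withSeed(seed, {
    parts <- lapply(split(seq_len(nrow(snpMap)), snpMap$chrom), function(ix) {
      chr <- snpMap$chrom[ix[1]]
      snpPos <- snpMap$pos[ix]
      locIdx <- which(lo$chromosome == chr)
      allPos <- sort(unique(c(snpPos, lo$position[locIdx])))
      knownIdx <- match(lo$position[locIdx], allPos)
      knownOrig <- origins[, locIdx, drop = FALSE]
      om <- .bridgeOrigins(allPos, knownIdx, knownOrig, nMembers, cMPerKb)
      refFreq <- colMeans(om == 1L)[match(snpPos, allPos)]
      p <- refFreq * (1 - errorRate) + (1 - refFreq) * errorRate
      depth <- stats::rpois(length(ix), meanDepth)
      refCount <- stats::rbinom(length(ix), depth, p)
      data.frame(chrom = chr, pos = snpPos,
                 ref = snpMap$ref[ix], var = snpMap$var[ix],
                 refCount = refCount, varCount = depth - refCount)
    })
    out <- do.call(rbind, parts)
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
  })
}

#' Construct a mosaic (backcrossed) haplotype over a SNP map
#'
#' Marks which SNPs of a recipient genome have been replaced by donor
#' segments, as in a strain derived from repeated backcrossing that retains
#' only a few donor chromosome segments.
#'
#' @param donorSegments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, 1-based inclusive); non-overlapping and sorted.
#' @param snpMap SNP map from \code{\link{makeSnpMap}}.
#' @return The SNP map with an added \code{origin} column ("donor" or
#'   "recipient") and the ground-truth segment list attached as attribute
#'   \code{segments}.
#' @export
generateMosaicGenome <- function(donorSegments, snpMap) {
  donorSegments <- as.data.frame(donorSegments)
  if (nrow(donorSegments)) {
    for (chr in unique(donorSegments$chrom)) {
      s <- donorSegments[donorSegments$chrom == chr, , drop = FALSE]
      s <- s[order(s$start), ]
      if (any(s$end < s$start) ||
          (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])))
        stopf("donor segments on %s must be sorted and non-overlapping", chr)
    }
  }
  origin <- rep("recipient", nrow(snpMap))
  for (i in seq_len(nrow(donorSegments))) {
    hit <- snpMap$chrom == donorSegments$chrom[i] &
      snpMap$pos >= donorSegments$start[i] &
      snpMap$pos <= donorSegments$end[i]
    origin[hit] <- "donor"
  }
  out <- cbind(snpMap, origin = origin)
  attr(out, "segments") <- donorSegments
  out
}

#' Simulate pooled read counts for a backcross-derived pool
#'
#' Crosses a mosaic strain (see \code{\link{generateMosaicGenome}}) to the
#' reference-genome strain and simulates pooled sequencing of viable progeny.
#' SNPs outside donor segments are homozygous reference in the cross and stay
#' fixed near frequency 1; SNPs inside donor segments segregate.
#'
#' @param mosaic Output of \code{\link{generateMosaicGenome}}.
#' @param nColonies Pool size.
#' @param meanDepth Mean depth per SNP.
#' @param seed Integer seed.
#' @param cMPerKb Recombination rate along the chromosome.
#' @return Allele-count table (as \code{\link{simulatePoolReadcounts}}).
#' @export
simulateBackcrossPoolCounts <- function(mosaic, nColonies = 150,
                                        meanDepth = 15, seed = 1,
                                        cMPerKb = 0.16) {
  withSeed(seed, {
    parts <- lapply(split(seq_len(nrow(mosaic)), mosaic$chrom), function(ix) {
      chr <- mosaic$chrom[ix[1]]
      pos <- mosaic$pos[ix]
      donor <- mosaic$origin[ix] == "donor"
      # parent-of-origin chains (1 = mosaic parent, 2 = reference parent)
      om <- .bridgeOrigins(pos, integer(), matrix(0L, nColonies, 0),
                           nColonies, cMPerKb)
      # allele is the variant only where the member inherited the mosaic
      # parent AND the mosaic parent carries donor sequence there
      isVar <- sweep(om == 1L, 2, donor, `&`)
      refFreq <- 1 - colMeans(isVar)
      depth <- stats::rpois(length(ix), meanDepth)
      refCount <- stats::rbinom(length(ix), depth, refFreq)
      data.frame(chrom = chr, pos = pos,
                 ref = mosaic$ref[ix], var = mosaic$var[ix],
                 refCount = refCount, varCount = depth - refCount)
    })
    out <- do.call(rbind, parts)
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
  })
}
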