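# Generators: tetrads, pools, read counts, mosaics.

test_that("tetrad simulation respects viability and 2:2 segregation", {
  # no killers: every spore viable
  noKiller <- crossConfig(
    data.frame(id = "m", chromosome = "I", position = 1e5),
    parent1 = c(m = "A"), parent2 = c(m = "B"))
  tt <- simulateMeiosisTetrads(noKiller, 40, seed = 1)
  expect_equal(nrow(tt), 160)
  expect_true(all(tt$viable))

  # fully penetrant het killer: every tetrad exactly 2 viable
  tt <- simulateMeiosisTetrads(hetKillerCross(), 200, seed = 2)
  perTetrad <- tapply(tt$viable, tt$tetradId, sum)
  expect_true(all(perTetrad == 2))

  # marginal allele ratio among ALL spores is exactly 2:2 per tetrad
  cfg <- mutualKillerCross(linked = TRUE, r = 0.2)
  tt <- simulateMeiosisTetrads(cfg, 100, seed = 3)
  for (loc in c("a", "b")) {
    perTetrad <- tapply(tt[[loc]], tt$tetradId,
                        function(g) max(table(g)))
    expect_true(all(perTetrad == 2))
  }

  # dead spores can be reported ungenotyped
  tt <- simulateMeiosisTetrads(hetKillerCross(), 20, seed = 4,
                               hideDeadGenotypes = TRUE)
  expect_true(all(is.na(tt$k[!tt$viable])))
  expect_true(all(!is.na(tt$k[tt$viable])))
})

test_that("generators are bitwise reproducible by seed", {
  cfg <- mutualKillerCross(linked = TRUE, r = 0.1)
  expect_identical(simulateMeiosisTetrads(cfg, 50, seed = 11),
                   simulateMeiosisTetrads(cfg, 50, seed = 11))
  expect_identical(makeSnpMap(c(I = 5e5, II = 3e5), seed = 7),
                   makeSnpMap(c(I = 5e5, II = 3e5), seed = 7))
  plans <- list(syntheticGenePlan("g1", hasIntron1Motif = TRUE,
                                  plantedAtg = "intron1"))
  expect_identical(generateWtfFamily(plans, seed = 9)$sequences,
                   generateWtfFamily(plans, seed = 9)$sequences)
  pool <- simulateViableSporePool(hetKillerCross(), 30, seed = 13)
  snp <- makeSnpMap(c(III = 5e5), seed = 13)
  expect_identical(simulatePoolReadcounts(pool, snp, seed = 14),
                   simulatePoolReadcounts(pool, snp, seed = 14))
})

test_that("viable-spore pools reflect killer selection", {
  # fully penetrant killer: every colony carries it
  pool <- simulateViableSporePool(hetKillerCross(), 150, seed = 21)
  expect_true(all(pool$k == "cw9"))

  # unlinked marker stays near 50%
  loci <- data.frame(id = c("k", "m"), chromosome = c("III", "I"),
                     position = c(1e6, 1e6))
  cfg <- crossConfig(loci, parent1 = c(k = "+", m = "A"),
                     parent2 = c(k = "cw9", m = "B"),
                     killers = list(killerAllele("cw9", "k")))
  pool <- simulateViableSporePool(cfg, 400, seed = 22)
  f <- mean(pool$m == "A")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 400))

  # partial penetrance: non-carrier frequency matches the enumeration
  cfg6 <- hetKillerCross(kappa = 0.6)
  pool <- simulateViableSporePool(cfg6, 600, seed = 23)
  fHat <- mean(pool$k == "+")
  fExp <- expectedViableAlleleFrequency(cfg6, "k", "+")
  expect_lt(abs(fHat - fExp), 3 * sqrt(fExp * (1 - fExp) / 600))

  # zero viability errors out after bounded attempts
  expect_error(
    simulateViableSporePool(mutualKillerCross(linked = TRUE, r = 0), 5,
                            seed = 24, maxAttempts = 200),
    "viability")
})

test_that("pooled read counts follow the depth and frequency model", {
  snp <- makeSnpMap(c(III = 2e6), densityPer100kb = 250, seed = 31)  # 5000 SNPs
  expect_equal(nrow(snp), 5000)
  expect_true(all(diff(snp$pos) > 0))
  expect_true(all(snp$ref != snp$var))

  pool <- simulateViableSporePool(hetKillerCross(), 100, seed = 32)
  counts <- simulatePoolReadcounts(pool, snp, meanDepth = 15, seed = 33)
  obsDepth <- mean(counts$refCount + counts$varCount)
  expect_lt(abs(obsDepth - 15) / 15, 0.02)

  # a pool fixed for the reference allele yields no variant reads
  mosaic <- generateMosaicGenome(
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    snp)
  fixed <- simulateBackcrossPoolCounts(mosaic, nColonies = 50,
                                       meanDepth = 12, seed = 34)
  expect_true(all(fixed$varCount == 0))
})

test_that("mosaic genomes mark donor segments correctly", {
  snp <- makeSnpMap(c(III = 2e6), densityPer100kb = 100, seed = 41)
  segs <- data.frame(chrom = "III", start = c(247743, 814348),
                     end = c(568805, 1711635))
  mosaic <- generateMosaicGenome(segs, snp)
  inSeg <- (snp$pos >= 247743 & snp$pos <= 568805) |
    (snp$pos >= 814348 & snp$pos <= 1711635)
  expect_equal(mosaic$origin == "donor", inSeg)
  # a SNP in the gap between the segments is recipient
  gapSnp <- which(snp$pos > 568805 & snp$pos < 814348)
  expect_true(all(mosaic$origin[gapSnp] == "recipient"))
  # overlap validation
  expect_error(
    generateMosaicGenome(
      data.frame(chrom = "III", start = c(100, 200), end = c(300, 400)), snp),
    "non-overlapping")
})
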