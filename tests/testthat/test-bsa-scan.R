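# Allele frequencies, rolling-median trend, distortion regions, donor
# segments.

countRow <- function(refC, varC, pos = seq_along(refC))
  data.frame(chrom = "III", pos = pos, ref = "A", var = "G",
             refCount = refC, varCount = varC)

test_that("allele frequencies apply the depth filter", {
  tab <- countRow(c(7, 4, 0), c(3, 5, 12))
  tr10 <- computeAlleleFrequencies(tab, minDepth = 10)
  expect_equal(tr10$refFreq, c(0.7, 0))      # the 9-read SNP is dropped
  expect_equal(nrow(tr10), 2)
  tr7 <- computeAlleleFrequencies(tab, minDepth = 7)
  expect_equal(nrow(tr7), 3)                 # retained at the lower cutoff
  expect_equal(tr7$refFreq[2], 4 / 9)
  expect_true(all(tr7$refFreq >= 0 & tr7$refFreq <= 1))
  expect_error(computeAlleleFrequencies(countRow(-1, 5)), "non-negative")
})

test_that("rolling median matches a sort-per-window oracle", {
  mkTrack <- function(f) data.frame(chrom = "c", pos = seq_along(f),
                                    refFreq = f)
  # constant series
  tr <- rollingMedianTrend(mkTrack(rep(0.5, 60)), 45)
  expect_true(all(tr$trend[23:38] == 0.5))
  expect_true(all(is.na(tr$trend[1:22])))
  expect_true(all(is.na(tr$trend[39:60])))

  # worked example, window 3
  tr <- rollingMedianTrend(mkTrack(c(1, 0, 1, 1, 0)), 3)
  expect_equal(tr$trend, c(NA, 1, 1, 1, NA))

  # a lone outlier does not move the median
  f <- rep(0.5, 101); f[51] <- 0
  tr <- rollingMedianTrend(mkTrack(f), 45)
  expect_true(all(tr$trend[23:79] == 0.5))

  # oracle: per-window sort and middle element
  set.seed(202)
  for (rep in 1:50) {
    n <- sample(50:200, 1)
    w <- sample(c(3, 5, 7, 9, 11, 21), 1)
    f <- runif(n)
    tr <- rollingMedianTrend(mkTrack(f), w)
    h <- (w - 1) / 2
    oracle <- rep(NA_real_, n)
    for (i in (h + 1):(n - h)) {
      win <- sort(f[(i - h):(i + h)])
      oracle[i] <- win[h + 1]
    }
    expect_equal(tr$trend, oracle)
  }

  # short chromosome: no trend, with a warning
  expect_warning(tr <- rollingMedianTrend(mkTrack(runif(10)), 45), "fewer")
  expect_true(all(is.na(tr$trend)))
  expect_error(rollingMedianTrend(mkTrack(runif(10)), 4), "odd")
})

test_that("distortion regions are called from trend deviations", {
  # flat at 0.5: nothing
  flat <- data.frame(chrom = "c", pos = 1:200, refFreq = 0.5)
  flat <- rollingMedianTrend(flat, 45)
  expect_equal(nrow(detectDistortionRegions(flat)), 0)

  # single planted killer: one region containing the killer locus
  cfg <- hetKillerCross()
  attr(cfg, "chromLengths") <- c(III = 2e6)
  snp <- makeSnpMap(c(III = 2e6), densityPer100kb = 150, seed = 51)
  pool <- simulateViableSporePool(cfg, 150, seed = 52)
  counts <- simulatePoolReadcounts(pool, snp, meanDepth = 15, seed = 53)
  track <- rollingMedianTrend(computeAlleleFrequencies(counts))
  reg <- detectDistortionRegions(track)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$direction, "reference_underrepresented")
  expect_lt(abs(reg$extremumPos - 1e6), 1e5)

  # monotone in delta: stricter regions nest inside looser ones
  regLoose <- detectDistortionRegions(track, delta = 0.1)
  regStrict <- detectDistortionRegions(track, delta = 0.2)
  for (i in seq_len(nrow(regStrict))) {
    contained <- any(regLoose$chrom == regStrict$chrom[i] &
                     regLoose$start <= regStrict$start[i] &
                     regLoose$end >= regStrict$end[i])
    expect_true(contained)
  }
})

test_that("donor segments are recovered from backcross pools", {
  # all-reference track: no segments
  track <- data.frame(chrom = "c", pos = 1:100, refFreq = 1)
  expect_equal(nrow(inferDonorSegments(track)), 0)

  # mosaic recovery within one inter-SNP gap of the planted boundaries
  snp <- makeSnpMap(c(III = 2e6), densityPer100kb = 100, seed = 61)
  segs <- data.frame(chrom = "III", start = c(247743, 814348),
                     end = c(568805, 1711635))
  mosaic <- generateMosaicGenome(segs, snp)
  counts <- simulateBackcrossPoolCounts(mosaic, nColonies = 150,
                                        meanDepth = 15, seed = 62)
  track <- computeAlleleFrequencies(counts)
  found <- inferDonorSegments(track)
  expect_equal(nrow(found), 2)
  for (i in 1:2) {
    gapBefore <- max(diff(snp$pos))  # most permissive inter-SNP gap
    expect_lt(abs(found$start[i] - segs$start[i]), gapBefore + 1)
    expect_lt(abs(found$end[i] - segs$end[i]), gapBefore + 1)
  }

  # whole-genome donor cross: one segment per chromosome spanning all SNPs
  snp2 <- makeSnpMap(c(I = 5e5, II = 5e5), densityPer100kb = 50, seed = 63)
  all <- generateMosaicGenome(
    data.frame(chrom = c("I", "II"), start = 1, end = 5e5), snp2)
  counts2 <- simulateBackcrossPoolCounts(all, nColonies = 150,
                                         meanDepth = 20, seed = 64)
  track2 <- computeAlleleFrequencies(counts2)
  found2 <- inferDonorSegments(track2)
  expect_equal(found2$chrom, c("I", "II"))
  for (chr in c("I", "II")) {
    sub <- track2[track2$chrom == chr, ]
    expect_equal(found2$start[found2$chrom == chr], min(sub$pos))
    expect_equal(found2$end[found2$chrom == chr], max(sub$pos))
  }
})
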