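# Bulk-segregant analysis: allele frequencies from pooled read counts,
# rolling-median trend, transmission-distortion regions, donor segments.

#' Reference-allele frequencies from an allele-count table
#'
#' Computes the reference-allele frequency at each SNP as the reference read
#' count divided by the summed reference and variant read counts, keeping
#' only SNPs whose summed count reaches the depth filter.
#'
#' @param counts Allele-count table: data.frame with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{var}, \code{refCount}, \code{varCount}.
#' @param minDepth Minimum summed ref+var read count for a SNP to be kept
#'   (default 10; lower-coverage pools may need 7).
#' @return Frequency track: the retained rows with an added \code{refFreq}
#'   column.
#' @examples
#' tab <- data.frame(chrom = "III", pos = c(100, 200), ref = "A", var = "G",
#'                   refCount = c(7, 4), varCount = c(3, 5))
#' computeAlleleFrequencies(tab)               # second row dropped
#' computeAlleleFrequencies(tab, minDepth = 7) # both retained
#' @export
computeAlleleFrequencies <- function(counts, minDepth = 10) {
  need <- c("chrom", "pos", "refCount", "varCount")
  if (!all(need %in% names(counts)))
    stopf("count table must have columns: %s", paste(need, collapse = ", "))
  if (any(counts$refCount < 0 | counts$varCount < 0))
    stopf("read counts must be non-negative")
  depth <- counts$refCount + counts$varCount
  out <- counts[depth >= minDepth, , drop = FALSE]
  out$refFreq <- out$refCount / (out$refCount + out$varCount)
  rownames(out) <- NULL
  out
}

#' Rolling-median trend of a frequency track
#'
#' Smooths reference-allele frequencies with a centered rolling median over a
#' fixed number of consecutive SNPs, computed per chromosome. The trend is
#' undefined (NA) at the \code{(window - 1)/2} SNPs at each chromosome end
#' where no full window fits; chromosomes with fewer SNPs than the window get
#' no trend at all (with a warning).
#'
#' @param track Frequency track from \code{\link{computeAlleleFrequencies}}.
#' @param window Odd window size in SNPs (default 45).
#' @return The track with an added \code{trend} column.
#' @export
rollingMedianTrend <- function(track, window = 45) {
  if (window < 3 || window %% 2 == 0)
    stopf("window must be an odd integer >= 3")
  trend <- rep(NA_real_, nrow(track))
  for (chr in unique(track$chrom)) {
    ix <- which(track$chrom == chr)
    if (length(ix) < window) {
      warnf("chromosome %s has %d SNPs, fewer than the window (%d); no trend",
            chr, length(ix), window)
      next
    }
    trend[ix] <- zoo::rollapply(track$refFreq[ix], width = window,
                                FUN = stats::median, fill = NA,
                                align = "center")
  }
  track$trend <- trend
  track
}

#' Detect transmission-distortion regions
#'
#' Finds runs of consecutive SNPs whose trend deviates from the Mendelian
#' expectation of 0.5 by more than \code{delta}. Same-direction runs
#' separated by fewer than \code{mergeGap} sub-threshold SNPs are merged
#' into one region (a brief return toward 0.5 shorter than the evidence
#' threshold does not terminate a region); merged regions carrying fewer
#' than \code{minRun} deviating SNPs are dropped. The direction reports
#' which parent's alleles are under-represented among viable progeny, and
#' the extremum is the position of maximal deviation within the region.
#'
#' @param track Track with a \code{trend} column
#'   (\code{\link{rollingMedianTrend}}).
#' @param delta Minimum absolute deviation of the trend from 0.5.
#' @param minRun Minimum number of deviating SNPs per region.
#' @param mergeGap Maximum sub-threshold gap (SNPs) bridged when merging;
#'   defaults to \code{minRun}.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (bp of the first/last deviating SNP), \code{direction}
#'   (\code{"reference_underrepresented"} or
#'   \code{"variant_underrepresented"}), \code{extremumPos},
#'   \code{extremumTrend}, \code{nSnps} (deviating SNPs). Empty when there
#'   is no signal.
#' @export
detectDistortionRegions <- function(track, delta = 0.15, minRun = 45,
                                    mergeGap = minRun) {
  if (is.null(track$trend)) stopf("track has no trend column")
  out <- list()
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    for (dir in c("low", "high")) {
      dev <- if (dir == "low") 0.5 - sub$trend else sub$trend - 0.5
      runs <- trueRuns(dev > delta, minLen = 1L)
      if (!nrow(runs)) next
      # merge runs separated by fewer than mergeGap sub-threshold SNPs
      grp <- cumsum(c(TRUE, runs$start[-1] - runs$end[-nrow(runs)] - 1L >=
                        mergeGap))
      for (g in unique(grp)) {
        rs <- runs[grp == g, , drop = FALSE]
        nDev <- sum(rs$end - rs$start + 1L)
        if (nDev < minRun) next
        span <- rs$start[1]:rs$end[nrow(rs)]
        ext <- span[which.max(dev[span])]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = sub$pos[rs$start[1]],
          end = sub$pos[rs$end[nrow(rs)]],
          direction = if (dir == "low") "reference_underrepresented"
                      else "variant_underrepresented",
          extremumPos = sub$pos[ext], extremumTrend = sub$trend[ext],
          nSnps = nDev)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), extremumPos = numeric(),
                      extremumTrend = numeric(), nSnps = integer()))
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Infer donor segments in a backcrossed strain
#'
#' In a pool from a backcrossed-strain x reference-strain cross, SNPs where
#' the backcrossed strain carries reference sequence are fixed for the
#' reference allele (frequency ~1), while SNPs inside retained donor segments
#' segregate. Maximal runs of SNPs with reference frequency at or below
#' \code{maxRefFreq}, of at least \code{minRun} SNPs, are reported as donor
#' segments bounded by the first and last SNP of the run. Runs separated by
#' fewer than \code{mergeGap} high-frequency SNPs are merged (a lone SNP
#' sampled at full reference frequency inside a segregating segment does not
#' split it); outside true donor segments every SNP sits at frequency ~1, so
#' real gaps are never bridged.
#'
#' @param track Frequency track (\code{\link{computeAlleleFrequencies}}).
#' @param maxRefFreq Maximum reference frequency for a SNP to count as
#'   segregating.
#' @param minRun Minimum number of segregating SNPs per segment.
#' @param mergeGap Maximum high-frequency gap (SNPs) bridged when merging.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{nSnps} (segregating SNPs).
#' @export
inferDonorSegments <- function(track, maxRefFreq = 0.95, minRun = 20,
                               mergeGap = minRun) {
  out <- list()
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    runs <- trueRuns(sub$refFreq <= maxRefFreq, minLen = 1L)
    if (!nrow(runs)) next
    grp <- cumsum(c(TRUE, runs$start[-1] - runs$end[-nrow(runs)] - 1L >=
                      mergeGap))
    for (g in unique(grp)) {
      rs <- runs[grp == g, , drop = FALSE]
      nSeg <- sum(rs$end - rs$start + 1L)
      if (nSeg < minRun) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = sub$pos[rs$start[1]],
        end = sub$pos[rs$end[nrow(rs)]],
        nSnps = nSeg)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), nSnps = integer()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write regions as BED
#'
#' Converts 1-based inclusive region coordinates to BED's 0-based half-open
#' convention and writes a three-column (plus name) BED file.
#'
#' @param regions Regions from \code{\link{detectDistortionRegions}} or
#'   \code{\link{inferDonorSegments}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  name <- if (!is.null(regions$direction)) regions$direction
          else rep("donor_segment", nrow(regions))
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = name)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
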