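# Synthetic wtf-like gene families with planted motifs, start codons, LTR
# flanks and pseudogenizing lesions. Construction is fully controlled so that
# every planted feature is recorded as exact ground truth.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.allCodons <- local({
  g <- expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)
  paste0(g[, 3], g[, 2], g[, 1])
})
.nonStopCodons <- setdiff(.allCodons, .STOPS)

# mutate a sequence at `rate` by random substitutions; returns character scalar
.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Plan a synthetic wtf-like gene
#'
#' Describes which features to plant in one synthetic gene of a family:
#' conserved upstream element (288 bp), the 150 bp intron-1 element, an
#' in-frame start codon for the short (poison) isoform, a pseudogenizing
#' lesion, and LTR flanks.
#'
#' @param geneId Gene id.
#' @param exonCount 5 or 6.
#' @param hasConservedUp Plant the 288 bp conserved upstream element.
#' @param hasIntron1Motif Plant the 150 bp element in intron 1.
#' @param plantedAtg Where to plant the first in-frame ATG downstream of the
#'   intron-1 element: \code{"none"}, \code{"intron1"} or \code{"exon2"}.
#' @param atgOffset For \code{"intron1"}: bp between the end of the ATG and
#'   the start of exon 2 (default 7). For \code{"exon2"}: bp from the start
#'   of exon 2 to the ATG.
#' @param plantedLesion One of \code{"none"}, \code{"lost_start"},
#'   \code{"premature_stop"}, \code{"frameshift_indel"},
#'   \code{"segmental_deletion"}.
#' @param ltrFlanks \code{"none"}, \code{"single"} or
#'   \code{"directly_oriented_pair"}.
#' @return A plan (list) consumed by \code{\link{generateWtfFamily}}.
#' @export
syntheticGenePlan <- function(geneId, exonCount = 6, hasConservedUp = TRUE,
                              hasIntron1Motif = FALSE,
                              plantedAtg = c("none", "intron1", "exon2"),
                              atgOffset = 7,
                              plantedLesion = c("none", "lost_start",
                                                "premature_stop",
                                                "frameshift_indel",
                                                "segmental_deletion"),
                              ltrFlanks = c("none", "single",
                                            "directly_oriented_pair")) {
  plantedAtg <- match.arg(plantedAtg)
  plantedLesion <- match.arg(plantedLesion)
  ltrFlanks <- match.arg(ltrFlanks)
  stopifnot(exonCount %in% c(5, 6), atgOffset >= 0)
  if (plantedAtg == "intron1" && atgOffset < 2)
    stopf("an intron-1 ATG needs atgOffset >= 2 (splice acceptor occupies the last 2 bp)")
  if (hasIntron1Motif && plantedAtg == "none")
    stopf("a gene with the intron-1 element needs a planted ATG (its poison-isoform start)")
  list(geneId = geneId, exonCount = exonCount,
       hasConservedUp = hasConservedUp, hasIntron1Motif = hasIntron1Motif,
       plantedAtg = plantedAtg, atgOffset = atgOffset,
       plantedLesion = plantedLesion, ltrFlanks = ltrFlanks)
}

# expected classification for a plan (the generator's ground truth)
.planTruthCategory <- function(plan) {
  if (plan$plantedLesion != "none") return("pseudogene")
  if (plan$hasIntron1Motif) {
    if (plan$plantedAtg == "intron1") return("poison_and_antidote_intron1_atg")
    return("poison_and_antidote_exon2_atg")
  }
  if (plan$plantedAtg == "none") return("antidote_only")
  "divergent_unclassified"
}

# delete positions from..to of a gene: returns list(seqChars, features)
.deleteRange <- function(ch, features, from, to) {
  w <- to - from + 1L
  ch <- ch[-(from:to)]
  keep <- !(features$start >= from & features$end <= to)
  features <- features[keep, , drop = FALSE]
  features$start <- ifelse(features$start > to, features$start - w,
                           ifelse(features$start >= from, from, features$start))
  features$end <- ifelse(features$end > to, features$end - w,
                         ifelse(features$end >= from, from - 1L, features$end))
  list(ch = ch, features = features)
}

# one gene: returns list(seq, features, model, truth)
.buildGene <- function(plan, fam, divergence, ltrJunction, ltrHomology) {
  exLens <- if (plan$exonCount == 6) c(240, 147, 120, 162, 201, 99)
            else c(240, 147, 120, 162, 99)
  # frame conditions for the planted start codon
  if (plan$plantedAtg == "intron1") {
    exLens[1] <- exLens[1] + (plan$atgOffset - exLens[1]) %% 3
  } else if (plan$plantedAtg == "exon2") {
    exLens[1] <- exLens[1] + (-plan$atgOffset - exLens[1]) %% 3
  }
  total <- sum(exLens)
  exLens[length(exLens)] <- exLens[length(exLens)] + (3 - total %% 3) %% 3
  cdsLen <- sum(exLens)
  L1 <- exLens[1]

  # CDS: ATG + non-stop codons + TAA, with Met excluded from the first
  # 150 bp of exon 2 except where planted
  nCodons <- cdsLen / 3
  codons <- c("ATG", sample(.nonStopCodons, nCodons - 2, replace = TRUE), "TAA")
  exon2Window <- which((3 * (seq_len(nCodons) - 1)) >= L1 &
                       (3 * (seq_len(nCodons) - 1)) < L1 + 150)
  for (i in setdiff(exon2Window, 1))
    if (codons[i] == "ATG")
      codons[i] <- sample(setdiff(.nonStopCodons, "ATG"), 1)
  if (plan$plantedAtg == "exon2")
    codons[(L1 + plan$atgOffset) / 3 + 1] <- "ATG"
  cds <- paste(codons, collapse = "")
  exonSeqs <- substring(cds, cumsum(c(0, exLens[-length(exLens)])) + 1,
                        cumsum(exLens))

  # intron 1: splice pad, optional 150 bp element, gap, optional planted ATG
  motifSeq <- if (plan$hasIntron1Motif)
    .mutateSeq(fam$intron1Motif, fam$motifDivergence) else .randSeq(150)
  intron1Parts <- c("GT", .randSeq(20), motifSeq, .randSeq(30))
  if (plan$plantedAtg == "intron1")
    intron1Parts <- c(intron1Parts, "ATG", .randSeq(plan$atgOffset))
  else
    intron1Parts <- c(intron1Parts, .randSeq(40))
  intron1 <- paste(intron1Parts, collapse = "")
  substr(intron1, nchar(intron1) - 1, nchar(intron1)) <- "AG"
  motifStartInIntron1 <- 23L

  otherIntrons <- replicate(plan$exonCount - 2,
                            paste0("GT", .randSeq(44), "AG"))

  conservedUp <- if (plan$hasConservedUp)
    .mutateSeq(fam$conservedUp, fam$motifDivergence) else .randSeq(288)
  ltrUp <- ltrDown <- NULL
  if (plan$ltrFlanks != "none") ltrUp <- fam$ltr
  if (plan$ltrFlanks == "directly_oriented_pair") {
    # second copy: diverged from the first except for a perfect homology
    # window right after the junction position
    ch <- strsplit(fam$ltr, "")[[1]]
    protect <- (ltrJunction + 1):(ltrJunction + ltrHomology)
    forceDiff <- c(ltrJunction, ltrJunction + ltrHomology + 1)
    mut <- which(stats::runif(length(ch)) < 0.08)
    mut <- union(setdiff(mut, protect), forceDiff)
    for (i in mut) ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
    ltrDown <- paste(ch, collapse = "")
  }

  # assemble segments left to right
  segs <- list()
  addSeg <- function(type, seq) segs[[length(segs) + 1L]] <<- list(type, seq)
  if (!is.null(ltrUp)) addSeg("LTR", ltrUp)
  addSeg("pad", .mutateSeq(.randSeq(80), divergence))
  addSeg("conserved_up", conservedUp)
  addSeg("pad", .mutateSeq(.randSeq(40), divergence))
  for (i in seq_len(plan$exonCount)) {
    addSeg("exon", exonSeqs[i])
    if (i == 1L) addSeg("intron", intron1)
    else if (i < plan$exonCount)
      addSeg("intron", .mutateSeq(otherIntrons[i - 1], divergence))
  }
  addSeg("pad", .mutateSeq(.randSeq(60), divergence))
  if (!is.null(ltrDown)) addSeg("LTR", ltrDown)

  lens <- vapply(segs, function(s) nchar(s[[2]]), 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  types <- vapply(segs, `[[`, "", 1)
  features <- data.frame(type = types, start = starts, end = ends,
                         strand = "+", stringsAsFactors = FALSE)
  exonIdx <- which(features$type == "exon")
  features$type[exonIdx] <- paste0("exon", seq_along(exonIdx))
  intron1Row <- which(types == "intron")[1]
  motifStart <- features$start[intron1Row] + motifStartInIntron1 - 1L
  if (plan$hasIntron1Motif)
    features <- rbind(features,
                      data.frame(type = "intron1_motif", start = motifStart,
                                 end = motifStart + 149L, strand = "+"))
  seq <- paste(vapply(segs, `[[`, "", 2), collapse = "")
  ch <- strsplit(seq, "")[[1]]

  exonRows <- grep("^exon", features$type)
  e1 <- features[exonRows[1], ]; e2 <- features[exonRows[2], ]

  # sanitize the ATG scan region (intron 1 downstream of the element, or the
  # whole intron when there is none): no in-frame ATG other than the planted
  # one. In-frame for an intron position means the reading frame that
  # continues into exon 2 matches the CDS frame.
  plantedPos <- NA_integer_
  if (plan$plantedAtg == "intron1")
    plantedPos <- e2$start - plan$atgOffset - 3L
  scanFrom <- if (plan$hasIntron1Motif) motifStart + 150L
              else features$start[intron1Row]
  for (p in scanFrom:(e2$start - 3L)) {
    if (!is.na(plantedPos) && p == plantedPos) next
    if (ch[p] == "A" && ch[p + 1] == "T" && ch[p + 2] == "G" &&
        (e2$start - p - 3L - L1) %% 3 == 0)
      ch[p + 2] <- "C"
  }

  truth <- data.frame(
    geneId = plan$geneId, category = .planTruthCategory(plan),
    exonCount = plan$exonCount, atgLocation = plan$plantedAtg,
    atgDistance = if (plan$plantedAtg == "intron1") plan$atgOffset else NA,
    lesion = plan$plantedLesion, ltrFlanks = plan$ltrFlanks,
    stringsAsFactors = FALSE)

  # lesions (sequence surgery after assembly; coordinates updated)
  if (plan$plantedLesion == "lost_start") {
    ch[e1$start] <- "C"
  } else if (plan$plantedLesion == "premature_stop") {
    # a codon-aligned position inside exon 3 (~40% of the CDS, well before
    # the final 10%)
    e3cds <- L1 + exLens[2]                     # CDS offset of exon 3 start
    cdsPos <- e3cds + 30 + (3 - (e3cds + 30) %% 3) %% 3
    e3 <- features[exonRows[3], ]
    gpos <- e3$start + (cdsPos - e3cds)
    ch[gpos:(gpos + 2)] <- c("T", "A", "A")
  } else if (plan$plantedLesion == "frameshift_indel") {
    e3 <- features[exonRows[3], ]
    cut <- e3$start + 40L
    del <- .deleteRange(ch, features, cut, cut)
    ch <- del$ch; features <- del$features
  } else if (plan$plantedLesion == "segmental_deletion") {
    e4 <- features[exonRows[4], ]
    del <- .deleteRange(ch, features, e4$start - 10L, e4$end + 10L)
    ch <- del$ch; features <- del$features
  }

  exonRows <- grep("^exon", features$type)
  model <- geneModel(plan$geneId,
                     IRanges::IRanges(start = features$start[exonRows],
                                      end = features$end[exonRows]),
                     genomeId = "synthetic")
  list(seq = paste(ch, collapse = ""), features = features, model = model,
       truth = truth)
}

#' Generate a synthetic wtf-like gene family
#'
#' Builds gene sequences with the requested planted elements: a shared 288 bp
#' conserved upstream element, a shared 150 bp intron-1 element, in-frame
#' poison-isoform start codons in intron 1 or exon 2, pseudogenizing lesions,
#' and LTR flanks (directly oriented pairs carry a plantable perfect homology
#' window at the recombination junction). Every planted feature is emitted as
#' ground truth.
#'
#' @param plans List of plans from \code{\link{syntheticGenePlan}}.
#' @param seed Integer seed (bitwise-reproducible output).
#' @param divergence Substitution rate applied to non-critical regions
#'   (flanks, pads, later introns).
#' @param motifDivergence Substitution rate applied to each gene's copy of
#'   the shared elements.
#' @param ltrJunction,ltrHomology Position (bp within the LTR) of the planted
#'   recombination junction of directly oriented LTR pairs, and the length of
#'   the perfect homology window spanning it.
#' @return List with \code{sequences} (named character vector), \code{models}
#'   (list of \linkS4class{GeneModel}), \code{features} (data.frame: gene,
#'   type, start, end, strand), \code{truth} (data.frame of planted ground
#'   truth), \code{motifs} (the family consensus elements as
#'   \code{\link{motifDefinition}}s), \code{consensusStructures} (expected
#'   exon counts/lengths keyed by exon count), and \code{ltrJunction},
#'   \code{ltrHomology}.
#' @export
generateWtfFamily <- function(plans, seed = 1, divergence = 0.02,
                              motifDivergence = 0.02,
                              ltrJunction = 150, ltrHomology = 7) {
  if (!is.null(plans$geneId)) plans <- list(plans)  # a single plan
  withSeed(seed, {
    fam <- list(conservedUp = .randSeq(288), intron1Motif = .randSeq(150),
                ltr = .randSeq(300), motifDivergence = motifDivergence)
    genes <- lapply(plans, .buildGene, fam = fam, divergence = divergence,
                    ltrJunction = ltrJunction, ltrHomology = ltrHomology)
    ids <- vapply(plans, `[[`, "", "geneId")
    features <- do.call(rbind, lapply(seq_along(genes), function(i)
      cbind(gene = ids[i], genes[[i]]$features)))
    list(
      sequences = setNames(vapply(genes, `[[`, "", "seq"), ids),
      models = setNames(lapply(genes, `[[`, "model"), ids),
      features = features,
      truth = do.call(rbind, lapply(genes, `[[`, "truth")),
      motifs = list(
        conservedUp = motifDefinition("conserved_up", fam$conservedUp,
                                      expectedContext = "upstream"),
        intron1 = motifDefinition("intron1_150bp", fam$intron1Motif,
                                  expectedContext = "intron1")),
      consensusStructures = list(
        "6" = list(exonCount = 6, exonLengths = c(240, 147, 120, 162, 201, 99)),
        "5" = list(exonCount = 5, exonLengths = c(240, 147, 120, 162, 99))),
      ltrJunction = ltrJunction, ltrHomology = ltrHomology)
  })
}

#' Apply LTR-mediated recombination to a synthetic gene
#'
#' Collapses a directly oriented LTR pair onto a single recombinant LTR,
#' deleting everything between the junction-equivalent points of the two
#' copies -- the string-surgery model of a solo-LTR deletion event.
#'
#' @param family Output of \code{\link{generateWtfFamily}}.
#' @param geneId A gene built with
#'   \code{ltrFlanks = "directly_oriented_pair"}.
#' @param junction Switch point j within the LTR: the recombinant LTR is the
#'   first j bases of the upstream copy followed by the remainder of the
#'   downstream copy. Defaults to the family's planted junction.
#' @return List with \code{sequence} (the recombinant region),
#'   \code{deletedStart}, \code{deletedEnd} (1-based donor coordinates of the
#'   deleted interval), and \code{ltr} (coordinates of the solo LTR in the
#'   recombinant).
#' @export
applyLtrRecombination <- function(family, geneId, junction = NULL) {
  if (is.null(junction)) junction <- family$ltrJunction
  junction <- as.integer(junction)
  fe <- family$features[family$features$gene == geneId, ]
  ltrs <- fe[fe$type == "LTR", ]
  if (nrow(ltrs) != 2L) stopf("gene %s does not carry an LTR pair", geneId)
  seq <- family$sequences[[geneId]]
  sA <- ltrs$start[1]; sB <- ltrs$start[2]
  delStart <- sA + junction
  delEnd <- sB + junction - 1L
  recomb <- paste0(substr(seq, 1, delStart - 1L),
                   substr(seq, delEnd + 1L, nchar(seq)))
  list(sequence = recomb, deletedStart = delStart, deletedEnd = delEnd,
       ltr = c(start = sA, end = sA + (ltrs$end[1] - ltrs$start[1])))
}
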