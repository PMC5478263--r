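# Sequence-feature classification of wtf-like genes.

#' Define a motif for ungapped identity scanning
#'
#' @param id Motif id, e.g. \code{"conserved_up"} (288 bp) or
#'   \code{"intron1_150bp"} (150 bp).
#' @param consensus Consensus sequence (character scalar).
#' @param minIdentity Minimum fraction identity for a hit.
#' @param expectedContext Where the motif is expected: \code{"upstream"} or
#'   \code{"intron1"}.
#' @return A motif definition (list).
#' @export
motifDefinition <- function(id, consensus, minIdentity = 0.8,
                            expectedContext = c("upstream", "intron1")) {
  stopifnot(nchar(consensus) > 0, minIdentity > 0, minIdentity <= 1)
  expectedContext <- match.arg(expectedContext)
  structure(list(id = id, consensus = toupper(consensus),
                 minIdentity = minIdentity,
                 expectedContext = expectedContext),
            class = "MotifDefinition")
}

#' Scan a sequence for a motif by ungapped identity
#'
#' Slides the motif consensus along the sequence, computes the fraction of
#' identical bases per window, and reports non-overlapping hits at or above
#' the identity threshold (best hits first; overlapping weaker windows are
#' suppressed).
#'
#' @param sequence Character scalar (or \code{DNAString}).
#' @param motif A \code{\link{motifDefinition}}.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{identity}; zero rows when there is no hit.
#' @export
scanMotif <- function(sequence, motif) {
  sequence <- toupper(as.character(sequence))
  m <- motif$consensus
  L <- nchar(m); n <- nchar(sequence)
  if (n < L) stopf("sequence (%d bp) shorter than motif (%d bp)", n, L)
  seqCh <- strsplit(sequence, "")[[1]]
  motCh <- strsplit(m, "")[[1]]
  # identity per window via one vectorized pass per motif position
  matches <- integer(n - L + 1L)
  for (j in seq_len(L))
    matches <- matches + (seqCh[j:(n - L + j)] == motCh[j])
  ident <- matches / L
  cand <- which(ident >= motif$minIdentity)
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(),
                      identity = numeric()))
  cand <- cand[order(-ident[cand], cand)]
  taken <- logical(n)
  hits <- list()
  for (p in cand) {
    if (any(taken[p:(p + L - 1L)])) next
    taken[p:(p + L - 1L)] <- TRUE
    hits[[length(hits) + 1L]] <- data.frame(start = p, end = p + L - 1L,
                                            identity = ident[p])
  }
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

#' Locate the first in-frame ATG downstream of a position
#'
#' Scans from \code{fromPosition} for the first ATG codon whose reading frame
#' matches the predicted coding sequence. For positions inside intron 1 the
#' frame is computed as if translation continued through the remaining intron
#' into exon 2 (the short poison isoform would begin with a few
#' intron-1-encoded residues); for positions inside exon 2 it is the CDS
#' codon frame. The search extends at most \code{exon2DepthLimit} bp into
#' exon 2.
#'
#' @param gene A \linkS4class{GeneModel}.
#' @param sequence The gene region sequence (gene-forward).
#' @param fromPosition 1-based position at which to start scanning; must lie
#'   before the start of exon 2.
#' @param exon2DepthLimit How far into exon 2 to search (bp, default 150).
#' @return List with \code{location} (\code{"intron1"}, \code{"exon2"} or
#'   \code{"none"}), \code{position} (start of the ATG, NA if none),
#'   \code{distanceToExon2} (bp between the end of an intron-1 ATG and the
#'   start of exon 2; NA otherwise), \code{inFrame} (TRUE for any hit).
#' @export
locateFirstInframeAtg <- function(gene, sequence, fromPosition,
                                  exon2DepthLimit = 150) {
  sequence <- toupper(as.character(sequence))
  ex <- exonRanges(gene)
  if (length(ex) < 2L) stopf("gene %s has fewer than 2 exons", gene@geneId)
  e1End <- IRanges::end(ex)[1]
  e2Start <- IRanges::start(ex)[2]
  e2End <- IRanges::end(ex)[2]
  L1 <- IRanges::width(ex)[1]
  if (fromPosition >= e2Start)
    stopf("fromPosition (%d) is beyond the start of exon 2 (%d)",
          fromPosition, e2Start)
  ch <- strsplit(sequence, "")[[1]]
  none <- list(location = "none", position = NA_integer_,
               distanceToExon2 = NA_integer_, inFrame = NA)

  # intron 1: ATG fully inside the intron, frame continuing into exon 2
  pStart <- max(fromPosition, e1End + 1L)
  if (pStart <= e2Start - 3L) {
    for (p in pStart:(e2Start - 3L)) {
      if (ch[p] == "A" && ch[p + 1] == "T" && ch[p + 2] == "G" &&
          (e2Start - p - 3L - L1) %% 3 == 0) {
        return(list(location = "intron1", position = p,
                    distanceToExon2 = e2Start - p - 3L, inFrame = TRUE))
      }
    }
  }
  # exon 2: ATG at a CDS codon boundary within the depth limit
  lim <- min(exon2DepthLimit, e2End - e2Start + 1L)
  offs <- seq(from = (3 - L1 %% 3) %% 3, to = lim - 3L, by = 3)
  for (o in offs) {
    p <- e2Start + o
    if (ch[p] == "A" && ch[p + 1] == "T" && ch[p + 2] == "G")
      return(list(location = "exon2", position = p,
                  distanceToExon2 = NA_integer_, inFrame = TRUE))
  }
  none
}

# spliced CDS of a gene model
.splicedCds <- function(gene, sequence) {
  ex <- exonRanges(gene)
  paste(substring(as.character(sequence), IRanges::start(ex),
                  IRanges::end(ex)), collapse = "")
}

#' Call pseudogenizing lesions
#'
#' Compares a gene's predicted CDS against the family consensus structure and
#' reports lesions: \code{lost_start} (CDS does not begin with ATG),
#' \code{segmental_deletion} (an expected exon absent, or under half its
#' consensus length), \code{frameshift_indel} (spliced CDS length differs
#' from the consensus length modulo 3), and \code{premature_stop} (an
#' in-frame stop before the final 10\% of the consensus CDS; only evaluated
#' when the frame is intact, since stop cascades after an indel are
#' attributed to the indel).
#'
#' @param gene A \linkS4class{GeneModel}.
#' @param sequence The gene region sequence.
#' @param consensus List with \code{exonCount} and \code{exonLengths} (the
#'   family consensus exon structure).
#' @return Character vector of lesion labels (empty for an intact gene).
#' @export
callPseudogene <- function(gene, sequence, consensus) {
  lesions <- character()
  ex <- exonRanges(gene)
  consensusCdsLen <- sum(consensus$exonLengths)
  cds <- .splicedCds(gene, toupper(as.character(sequence)))

  if (substr(cds, 1, 3) != "ATG") lesions <- c(lesions, "lost_start")
  if (length(ex) < consensus$exonCount) {
    lesions <- c(lesions, "segmental_deletion")
  } else if (length(ex) == consensus$exonCount) {
    if (any(IRanges::width(ex) < 0.5 * consensus$exonLengths))
      lesions <- c(lesions, "segmental_deletion")
  }
  frameshift <- nchar(cds) %% 3 != consensusCdsLen %% 3
  if (frameshift) lesions <- c(lesions, "frameshift_indel")
  if (!frameshift && !"segmental_deletion" %in% lesions) {
    nCodons <- nchar(cds) %/% 3
    codons <- substring(cds, 3 * seq_len(nCodons) - 2, 3 * seq_len(nCodons))
    stops <- which(codons %in% .STOPS)
    cutoff <- 0.9 * consensusCdsLen / 3
    if (any(stops < cutoff)) lesions <- c(lesions, "premature_stop")
  }
  lesions
}

#' Classify a wtf-like gene
#'
#' Applies the classification precedence: (1) genes with lesions are
#' pseudogenes; (2) genes on the user-supplied divergent list are
#' \code{divergent_unclassified}; (3) genes carrying the 150 bp intron-1
#' element are poison-and-antidote genes, subtyped by the location of the
#' first in-frame ATG downstream of the element (intron 1 vs exon 2);
#' (4) genes with no in-frame ATG in intron 1 or the 5' section of exon 2
#' are antidote-only; (5) anything else is \code{divergent_unclassified}
#' with a reason.
#'
#' @param gene A \linkS4class{GeneModel}.
#' @param sequence The gene region sequence.
#' @param motifs List with an \code{intron1} \code{\link{motifDefinition}}
#'   (and optionally \code{conservedUp}, recorded as evidence only).
#' @param consensus Family consensus structure (see
#'   \code{\link{callPseudogene}}).
#' @param divergentList Optional character vector of gene ids to mark
#'   divergent.
#' @param exon2DepthLimit Depth of the exon-2 ATG search in bp.
#' @return A \linkS4class{ClassificationResult}.
#' @export
classifyGene <- function(gene, sequence, motifs, consensus,
                         divergentList = NULL, exon2DepthLimit = 150) {
  sequence <- toupper(as.character(sequence))
  id <- gene@geneId
  ex <- exonRanges(gene)
  lesions <- callPseudogene(gene, sequence, consensus)
  if (length(lesions)) {
    return(new("ClassificationResult", geneId = id, category = "pseudogene",
               reasons = paste0("lesion:", lesions),
               atgDistanceToExon2 = NA_real_))
  }
  if (id %in% divergentList) {
    return(new("ClassificationResult", geneId = id,
               category = "divergent_unclassified",
               reasons = "listed as divergent",
               atgDistanceToExon2 = NA_real_))
  }
  e1End <- IRanges::end(ex)[1]
  e2Start <- IRanges::start(ex)[2]
  intron1 <- substr(sequence, e1End + 1L, e2Start - 1L)
  hit <- if (nchar(intron1) >= nchar(motifs$intron1$consensus))
    scanMotif(intron1, motifs$intron1)
  else data.frame(start = integer(), end = integer(), identity = numeric())

  if (nrow(hit)) {
    motifEnd <- e1End + hit$end[1]
    atg <- locateFirstInframeAtg(gene, sequence, motifEnd + 1L,
                                 exon2DepthLimit)
    reasons <- sprintf("intron1 150bp element at %d-%d (identity %.3f)",
                       e1End + hit$start[1], motifEnd, hit$identity[1])
    if (atg$location == "intron1") {
      return(new("ClassificationResult", geneId = id,
                 category = "poison_and_antidote_intron1_atg",
                 reasons = c(reasons,
                             sprintf("in-frame ATG in intron 1, %d bp from exon 2",
                                     atg$distanceToExon2)),
                 atgDistanceToExon2 = as.numeric(atg$distanceToExon2)))
    }
    if (atg$location == "exon2") {
      return(new("ClassificationResult", geneId = id,
                 category = "poison_and_antidote_exon2_atg",
                 reasons = c(reasons, sprintf("first in-frame ATG in exon 2 at %d",
                                              atg$position)),
                 atgDistanceToExon2 = NA_real_))
    }
    return(new("ClassificationResult", geneId = id,
               category = "divergent_unclassified",
               reasons = c(reasons, "no in-frame ATG downstream of the element"),
               atgDistanceToExon2 = NA_real_))
  }
  atg <- locateFirstInframeAtg(gene, sequence, e1End + 1L, exon2DepthLimit)
  if (atg$location == "none") {
    return(new("ClassificationResult", geneId = id, category = "antidote_only",
               reasons = c("no intron-1 150bp element",
                           "no in-frame ATG in intron 1 or the 5' section of exon 2"),
               atgDistanceToExon2 = NA_real_))
  }
  new("ClassificationResult", geneId = id, category = "divergent_unclassified",
      reasons = sprintf("early in-frame ATG (%s) without the intron-1 element",
                        atg$location),
      atgDistanceToExon2 = NA_real_)
}

#' Classify every gene of a family
#'
#' @param family Output of \code{\link{generateWtfFamily}}, or a list with
#'   \code{sequences}, \code{models}, \code{motifs},
#'   \code{consensusStructures}.
#' @param divergentList,exon2DepthLimit Passed to \code{\link{classifyGene}}.
#' @return data.frame with columns \code{geneId}, \code{category},
#'   \code{atgDistanceToExon2}, \code{reasons} (collapsed with "; ").
#' @export
classifyFamily <- function(family, divergentList = NULL,
                           exon2DepthLimit = 150) {
  rows <- lapply(names(family$sequences), function(id) {
    gene <- family$models[[id]]
    # consensus structure keyed by the family's exon count for this gene;
    # ground-truth families record it, otherwise use the annotated count
    key <- if (!is.null(family$truth) && "exonCount" %in% names(family$truth))
      as.character(family$truth$exonCount[family$truth$geneId == id])
    else as.character(length(exonRanges(gene)))
    cons <- family$consensusStructures[[key]]
    if (is.null(cons)) stopf("no consensus structure for %d exons",
                             as.integer(key))
    res <- classifyGene(gene, family$sequences[[id]], family$motifs, cons,
                        divergentList, exon2DepthLimit)
    data.frame(geneId = res@geneId, category = res@category,
               atgDistanceToExon2 = res@atgDistanceToExon2,
               reasons = paste(res@reasons, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity of two aligned sequences
#'
#' Columns where both sequences are gaps are removed; the identity is the
#' number of identical non-gap columns divided by the remaining alignment
#' length.
#'
#' @param a,b Aligned sequences of equal length (gaps as \code{"-"}).
#' @return Fraction in \code{[0, 1]}.
#' @examples
#' pairwiseIdentity("ACGT-A", "ACGTTA")  # 5/6
#' @export
pairwiseIdentity <- function(a, b) {
  a <- strsplit(toupper(as.character(a)), "")[[1]]
  b <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(a) != length(b)) stopf("aligned sequences must have equal length")
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stopf("alignment has no non-gap columns")
  sum(a == b & a != "-") / length(a)
}

#' Detect an LTR-mediated deletion event
#'
#' Tests whether a single LTR in a recipient region is the recombination
#' product of a directly oriented LTR pair in a donor region: the recipient
#' LTR must be an exact prefix of the upstream donor copy joined to an exact
#' suffix of the downstream copy. Reports the deleted donor interval, the
#' range of switch points compatible with the sequences, and the breakpoint
#' homology (length of the perfectly matching window spanning the junction,
#' i.e. the ambiguity of the switch point).
#'
#' @param donorSeq Donor region sequence.
#' @param donorLtrs data.frame with columns \code{start}, \code{end},
#'   \code{strand} for the two donor LTR copies (gene-forward coordinates).
#' @param recipientSeq Recipient region sequence.
#' @param recipientLtr One-row data.frame (\code{start}, \code{end},
#'   \code{strand}) for the solo LTR at the syntenic position.
#' @return List with \code{detected} (logical); when TRUE also
#'   \code{deletedStart}, \code{deletedEnd} (donor coordinates, using the
#'   leftmost compatible switch point), \code{junctionRange} (compatible
#'   switch points within the LTR) and \code{homologyLength}; when FALSE a
#'   \code{reason} (no directly oriented pair, inverted orientation, or
#'   incompatible sequences).
#' @export
detectLtrDeletion <- function(donorSeq, donorLtrs, recipientSeq,
                              recipientLtr) {
  fail <- function(reason) list(detected = FALSE, reason = reason)
  if (nrow(donorLtrs) < 2L) return(fail("no LTR pair in donor"))
  donorLtrs <- donorLtrs[order(donorLtrs$start), ][1:2, ]
  if (donorLtrs$strand[1] != donorLtrs$strand[2])
    return(fail("donor LTRs are in inverted orientation"))
  A <- strsplit(toupper(substr(as.character(donorSeq), donorLtrs$start[1],
                               donorLtrs$end[1])), "")[[1]]
  B <- strsplit(toupper(substr(as.character(donorSeq), donorLtrs$start[2],
                               donorLtrs$end[2])), "")[[1]]
  R <- strsplit(toupper(substr(as.character(recipientSeq), recipientLtr$start[1],
                               recipientLtr$end[1])), "")[[1]]
  if (length(A) != length(B) || length(A) != length(R))
    return(fail("LTR copies differ in length"))
  mmA <- which(R != A)
  mmB <- which(R != B)
  jMax <- if (length(mmA)) min(mmA) - 1L else length(A)
  jMin <- if (length(mmB)) max(mmB) else 0L
  if (jMin > jMax)
    return(fail("recipient LTR is not a prefix/suffix recombinant of the donor pair"))
  list(detected = TRUE,
       deletedStart = donorLtrs$start[1] + jMin,
       deletedEnd = donorLtrs$start[2] + jMin - 1L,
       junctionRange = c(jMin, jMax),
       homologyLength = jMax - jMin)
}
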