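#' @import methods
#' @importFrom stats dbinom dhyper median optim rbinom rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

setOldClass("phylo")

#' KillerAllele: a poison-antidote spore-killer allele
#'
#' A killer allele expresses a trans-acting poison that kills spores of the
#' ascus, and a cis-restricted antidote that protects spores carrying the
#' allele. The model parameterizes each allele by its killing penetrance
#' \code{kappa} (probability that an unprotected spore exposed to the poison
#' dies), its antidote efficiency \code{pi} (probability that a carrier of the
#' allele is protected from a poison it resists), and a \code{resistanceSet} of
#' killer ids whose poison the antidote neutralizes. Two active killers with
#' disjoint resistance sets kill mutually: a spore inheriting only one of them
#' is killed by the other.
#'
#' @slot id Character label of the allele.
#' @slot locus Locus id at which the allele resides.
#' @slot kappa Killing penetrance in \code{[0, 1]}.
#' @slot pi Antidote efficiency in \code{[0, 1]}.
#' @slot resistanceSet Character vector of killer ids neutralized by this
#'   allele's antidote; contains the allele's own id by default.
#' @name KillerAllele-class
#' @aliases KillerAllele
#' @exportClass KillerAllele
setClass("KillerAllele",
  representation(id = "character", locus = "character",
                 kappa = "numeric", pi = "numeric",
                 resistanceSet = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a single non-empty string")
    if (length(object@locus) != 1L)
      msg <- c(msg, "locus must be a single locus id")
    if (length(object@kappa) != 1L || is.na(object@kappa) ||
        object@kappa < 0 || object@kappa > 1)
      msg <- c(msg, "kappa must be a single value in [0, 1]")
    if (length(object@pi) != 1L || is.na(object@pi) ||
        object@pi < 0 || object@pi > 1)
      msg <- c(msg, "pi must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a KillerAllele
#'
#' @param id Allele label (also the allele symbol used in parental genotypes).
#' @param locus Locus id where the allele resides.
#' @param kappa Killing penetrance in \code{[0, 1]}.
#' @param pi Antidote efficiency in \code{[0, 1]}.
#' @param resistanceSet Killer ids this allele's antidote neutralizes. Defaults
#'   to the allele's own id (self-resistance, no cross-resistance).
#' @return A \linkS4class{KillerAllele}.
#' @examples
#' killerAllele("cw9", locus = "L1")
#' @export
killerAllele <- function(id, locus, kappa = 1, pi = 1, resistanceSet = id) {
  new("KillerAllele", id = id, locus = locus, kappa = kappa, pi = pi,
      resistanceSet = resistanceSet)
}

#' Truncation-series killer presets
#'
#' Parameter bundles mirroring the phenotypes of the truncation series of
#' active killers: \code{Ta} and \code{Tc} are fully active
#' (\code{kappa = 1, pi = 1}); \code{Tb} has weakened protection
#' (\code{pi = 0.75}); \code{Td} has lost killing but retains protection
#' (\code{kappa = 0, pi = 1}); \code{Te} has more severely weakened protection
#' than Tb (\code{pi = 0.5}). The partial-protection values for Tb and Te are
#' representative choices on the qualitative ordering (1 > pi(Tb) > pi(Te)),
#' not measured quantities.
#'
#' @param preset One of \code{"Ta"}, \code{"Tb"}, \code{"Tc"}, \code{"Td"},
#'   \code{"Te"}.
#' @param id,locus Passed to \code{\link{killerAllele}}.
#' @return A \linkS4class{KillerAllele}.
#' @examples
#' killerPreset("Td", id = "cw27-Td", locus = "his3")
#' @export
killerPreset <- function(preset = c("Ta", "Tb", "Tc", "Td", "Te"), id, locus) {
  preset <- match.arg(preset)
  par <- switch(preset,
    Ta = c(1, 1), Tb = c(1, 0.75), Tc = c(1, 1), Td = c(0, 1), Te = c(1, 0.5))
  killerAllele(id, locus, kappa = par[1], pi = par[2])
}

setMethod("show", "KillerAllele", function(object) {
  cat(sprintf("KillerAllele %s @ %s: kappa=%g, pi=%g, resists {%s}\n",
              object@id, object@locus, object@kappa, object@pi,
              paste(object@resistanceSet, collapse = ", ")))
})

#' CrossConfig: a two-parent cross with killer alleles
#'
#' Describes a haploid-by-haploid cross: an ordered table of loci with linkage,
#' the two parental haplotypes, and the killer alleles segregating in the
#' diploid. Loci on the same chromosome are linked through per-interval
#' recombination fractions; loci on different chromosomes assort independently.
#'
#' @slot loci data.frame with columns \code{id}, \code{chromosome},
#'   \code{position} (bp, 1-based) and \code{recombFractionToNext}
#'   (fraction in \code{[0, 0.5]} to the next locus on the same chromosome;
#'   \code{NA} for the last locus of a chromosome).
#' @slot parent1,parent2 Named character vectors mapping locus id to the
#'   allele label carried by each parent.
#' @slot killers List of \linkS4class{KillerAllele}. A killer is present in
#'   the diploid when one of the parents carries its id as the allele at its
#'   locus.
#' @name CrossConfig-class
#' @aliases CrossConfig
#' @exportClass CrossConfig
setClass("CrossConfig",
  representation(loci = "data.frame", parent1 = "character",
                 parent2 = "character", killers = "list"),
  validity = function(object) {
    msg <- character()
    lo <- object@loci
    need <- c("id", "chromosome", "position", "recombFractionToNext")
    if (!all(need %in% names(lo)))
      return(paste("loci must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(lo$id)) msg <- c(msg, "duplicate locus ids")
    for (chr in unique(lo$chromosome)) {
      p <- lo$position[lo$chromosome == chr]
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("loci on chromosome %s not sorted by position", chr))
    }
    r <- lo$recombFractionToNext
    if (any(!is.na(r) & (r < 0 | r > 0.5)))
      msg <- c(msg, "recombination fractions must lie in [0, 0.5]")
    for (p in list(object@parent1, object@parent2)) {
      if (!setequal(names(p), lo$id))
        msg <- c(msg, "each parent must assign exactly one allele per locus")
    }
    for (k in object@killers) {
      if (!is(k, "KillerAllele")) {
        msg <- c(msg, "killers must be KillerAllele objects")
      } else if (!k@locus %in% lo$id) {
        msg <- c(msg, sprintf("killer %s locus %s not in loci", k@id, k@locus))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CrossConfig
#'
#' @param loci data.frame with columns \code{id}, \code{chromosome},
#'   \code{position}, and optionally \code{recombFractionToNext}. When the
#'   fraction column is absent it is computed from inter-locus physical
#'   distances with \code{\link{haldaneFraction}}.
#' @param parent1,parent2 Named character vectors (locus id to allele label).
#' @param killers List of \linkS4class{KillerAllele} objects.
#' @param cMPerKb Rate used when deriving recombination fractions from
#'   positions.
#' @return A \linkS4class{CrossConfig}.
#' @examples
#' cfg <- crossConfig(
#'   loci = data.frame(id = "k", chromosome = "III", position = 1e6),
#'   parent1 = c(k = "cw9"), parent2 = c(k = "+"),
#'   killers = list(killerAllele("cw9", "k")))
#' @export
crossConfig <- function(loci, parent1, parent2, killers = list(),
                        cMPerKb = 0.16) {
  loci <- as.data.frame(loci)
  loci <- loci[order(loci$chromosome, loci$position), , drop = FALSE]
  rownames(loci) <- NULL
  if (is.null(loci$recombFractionToNext)) {
    r <- rep(NA_real_, nrow(loci))
    if (nrow(loci) > 1L) {
      sameChr <- loci$chromosome[-1] == loci$chromosome[-nrow(loci)]
      d <- diff(loci$position)
      r[seq_len(nrow(loci) - 1L)][sameChr] <-
        haldaneFraction(d[sameChr], cMPerKb)
    }
    loci$recombFractionToNext <- r
  }
  loci$id <- as.character(loci$id)
  loci$chromosome <- as.character(loci$chromosome)
  new("CrossConfig", loci = loci,
      parent1 = structure(as.character(parent1), names = names(parent1)),
      parent2 = structure(as.character(parent2), names = names(parent2)),
      killers = killers)
}

setMethod("show", "CrossConfig", function(object) {
  cat(sprintf("CrossConfig: %d loci on %d chromosome(s), %d killer(s)\n",
              nrow(object@loci), length(unique(object@loci$chromosome)),
              length(object@killers)))
  for (k in object@killers) show(k)
})

#' @describeIn CrossConfig-class locus table accessor
#' @param x A \code{CrossConfig}.
#' @export
lociTable <- function(x) x@loci

#' @describeIn CrossConfig-class list of killers present in the diploid (an
#'   allele is present when either parent carries it at its locus)
#' @export
activeKillers <- function(x) {
  Filter(function(k) x@parent1[[k@locus]] == k@id || x@parent2[[k@locus]] == k@id,
         x@killers)
}

#' @describeIn CrossConfig-class parental haplotype accessor
#' @param which 1 or 2.
#' @export
parentHaplotype <- function(x, which = 1) {
  if (which == 1) x@parent1 else x@parent2
}

#' GeneModel: exon-intron structure of a wtf-like gene
#'
#' Coordinates are 1-based inclusive on the gene-forward strand of the
#' supplied sequence (i.e. position 1 is the first base of the region, and the
#' gene reads left to right).
#'
#' @slot geneId,genomeId,chromosome Character labels.
#' @slot strand "+" or "-" (orientation of the gene on its source chromosome;
#'   coordinates below are always gene-forward).
#' @slot exons \link[IRanges]{IRanges} of exon coordinates, sorted and
#'   non-overlapping; the predicted CDS is the concatenation of the exons.
#' @name GeneModel-class
#' @aliases GeneModel
#' @exportClass GeneModel
setClass("GeneModel",
  representation(geneId = "character", genomeId = "character",
                 chromosome = "character", strand = "character",
                 exons = "IRanges"),
  validity = function(object) {
    ex <- object@exons
    if (length(ex) < 1L) return("at least one exon required")
    st <- IRanges::start(ex); en <- IRanges::end(ex)
    if (is.unsorted(st, strictly = TRUE)) return("exons must be sorted")
    if (length(ex) > 1L && any(st[-1] <= en[-length(en)]))
      return("exons must be non-overlapping")
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    TRUE
  })

#' Construct a GeneModel
#'
#' @param geneId Gene id.
#' @param exons Two-column matrix/data.frame of (start, end), or an
#'   \code{IRanges}; 1-based inclusive, gene-forward.
#' @param genomeId,chromosome,strand Optional labels.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' geneModel("g1", cbind(start = c(101, 401), end = c(340, 700)))
#' @export
geneModel <- function(geneId, exons, genomeId = "synthetic",
                      chromosome = "chr", strand = "+") {
  if (!is(exons, "IRanges")) {
    exons <- as.data.frame(exons)
    exons <- IRanges::IRanges(start = exons[[1]], end = exons[[2]])
  }
  new("GeneModel", geneId = geneId, genomeId = genomeId,
      chromosome = chromosome, strand = strand, exons = exons)
}

#' @describeIn GeneModel-class exon ranges accessor
#' @param x A \code{GeneModel}.
#' @export
exonRanges <- function(x) x@exons

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s): %d exons, CDS %d bp\n", object@geneId,
              object@genomeId, length(object@exons),
              sum(IRanges::width(object@exons))))
})

#' ClassificationResult: category assigned to a wtf-like gene
#'
#' @slot geneId Gene id.
#' @slot category One of \code{poison_and_antidote_intron1_atg},
#'   \code{poison_and_antidote_exon2_atg}, \code{antidote_only},
#'   \code{pseudogene}, \code{divergent_unclassified}.
#' @slot reasons Character vector of evidence (motif hits, ATG location and
#'   frame, lesions).
#' @slot atgDistanceToExon2 bp from the end of an intron-1 start codon to the
#'   start of exon 2 (NA when not applicable).
#' @name ClassificationResult-class
#' @aliases ClassificationResult
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(geneId = "character", category = "character",
                 reasons = "character", atgDistanceToExon2 = "numeric"),
  validity = function(object) {
    cats <- c("poison_and_antidote_intron1_atg", "poison_and_antidote_exon2_atg",
              "antidote_only", "pseudogene", "divergent_unclassified")
    if (length(object@category) != 1L || !object@category %in% cats)
      return(paste("category must be one of:", paste(cats, collapse = ", ")))
    if (object@category == "pseudogene" && !any(grepl("^lesion:", object@reasons)))
      return("pseudogene classification requires at least one lesion reason")
    TRUE
  })

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("%s: %s\n  reasons: %s\n", object@geneId, object@category,
              paste(object@reasons, collapse = "; ")))
})

#' @describeIn ClassificationResult-class category accessor
#' @param x A \code{ClassificationResult}.
#' @export
geneCategory <- function(x) x@category

#' @describeIn ClassificationResult-class reasons accessor
#' @export
classificationReasons <- function(x) x@reasons

#' SupportedTree: phylogenetic tree with branch supports
#'
#' Wraps an \code{ape} \code{phylo} object whose internal node labels carry
#' bootstrap-style support values in \code{[0, 100]} (empty where missing).
#'
#' @slot tree A \code{phylo} object.
#' @name SupportedTree-class
#' @aliases SupportedTree
#' @exportClass SupportedTree
setClass("SupportedTree", representation(tree = "phylo"),
  validity = function(object) {
    tr <- object@tree
    if (anyDuplicated(tr$tip.label)) return("leaf labels must be unique")
    if (!is.null(tr$edge.length) && any(tr$edge.length < -1e-12))
      return("branch lengths must be non-negative")
    TRUE
  })

#' @describeIn SupportedTree-class underlying \code{phylo} accessor
#' @param x A \code{SupportedTree}.
#' @export
apeTree <- function(x) x@tree

#' @describeIn SupportedTree-class numeric support per internal node
#'   (NA where absent)
#' @export
nodeSupports <- function(x) {
  tr <- x@tree
  if (is.null(tr$node.label)) return(rep(NA_real_, tr$Nnode))
  suppressWarnings(as.numeric(tr$node.label))
}

setMethod("show", "SupportedTree", function(object) {
  tr <- object@tree
  cat(sprintf("SupportedTree: %d leaves, %d internal nodes, %d with support\n",
              length(tr$tip.label), tr$Nnode, sum(!is.na(nodeSupports(object)))))
})
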