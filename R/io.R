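# Readers and writers for the package's external formats: allele-count and
# tetrad TSVs, synteny maps, cross-config files (YAML), FASTA and GFF3.

#' Read an allele-count table
#'
#' Expects a tab-separated file with header columns \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{ref_count}, \code{alt_count}. Counts are
#' assumed to come from an upstream pipeline that already applied base- and
#' mapping-quality filters.
#'
#' @param path File path.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{var}, \code{refCount}, \code{varCount}.
#' @export
readCountTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(x)))
    stopf("count table must have header columns: %s",
          paste(need, collapse = ", "))
  data.frame(chrom = as.character(x$chrom), pos = x$pos, ref = x$ref,
             var = x$alt, refCount = x$ref_count, varCount = x$alt_count)
}

#' Write an allele-count table
#'
#' @param counts Internal count table (\code{refCount}/\code{varCount}
#'   columns).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  out <- data.frame(chrom = counts$chrom, pos = counts$pos, ref = counts$ref,
                    alt = counts$var, ref_count = counts$refCount,
                    alt_count = counts$varCount)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tetrad dissection table
#'
#' Tab-separated with header: \code{cross_id}, \code{tetrad_id},
#' \code{spore_index} (1-4), \code{viable} (0/1), then one column per marker
#' locus with \code{"."} for missing genotypes.
#'
#' @param path File path.
#' @return data.frame in the package's tetrad-record layout (\code{crossId},
#'   \code{tetradId}, \code{sporeIndex}, \code{viable}, marker columns).
#' @export
readTetradTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cross_id", "tetrad_id", "spore_index", "viable")
  if (!all(need %in% names(x)))
    stopf("tetrad table must have header columns: %s",
          paste(need, collapse = ", "))
  markers <- setdiff(names(x), need)
  out <- data.frame(crossId = x$cross_id, tetradId = x$tetrad_id,
                    sporeIndex = as.integer(x$spore_index),
                    viable = as.integer(x$viable) == 1L)
  for (m in markers) {
    v <- x[[m]]
    v[v == "."] <- NA
    out[[m]] <- v
  }
  out
}

#' Write a tetrad dissection table
#'
#' @param tetrads Tetrad records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTetradTable <- function(tetrads, path) {
  markers <- setdiff(names(tetrads),
                     c("crossId", "tetradId", "sporeIndex", "viable"))
  out <- data.frame(cross_id = tetrads$crossId, tetrad_id = tetrads$tetradId,
                    spore_index = tetrads$sporeIndex,
                    viable = as.integer(as.logical(tetrads$viable)))
  for (m in markers) {
    v <- as.character(tetrads[[m]])
    v[is.na(v)] <- "."
    out[[m]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a synteny map
#'
#' Tab-separated with header columns \code{gene}, \code{group}, and
#' optionally \code{genome}; when \code{genome} is absent it is taken as the
#' leading alphabetic prefix of the gene name (so e.g. cw- and wtf-prefixed
#' genes fall into two genomes).
#'
#' @param path File path.
#' @return data.frame with columns \code{gene}, \code{group}, \code{genome}.
#' @export
readSyntenyMap <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "group") %in% names(x)))
    stopf("synteny map must have header columns gene, group")
  if (is.null(x$genome)) x$genome <- sub("[0-9].*$", "", x$gene)
  x[, c("gene", "group", "genome")]
}

#' Read a cross configuration file
#'
#' YAML with keys \code{loci} (list of id/chromosome/position and optional
#' recombFractionToNext), \code{parent1}, \code{parent2} (locus: allele
#' maps), \code{killers} (list of id/locus plus either kappa/pi/resistanceSet
#' or a \code{preset} name Ta-Te), and optionally \code{chromosomes}
#' (name: length map used by simulators).
#'
#' @param path File path.
#' @return A \linkS4class{CrossConfig}; chromosome lengths, when present,
#'   are attached as attribute \code{chromLengths}.
#' @export
readCrossConfig <- function(path) {
  y <- yaml::read_yaml(path)
  loci <- do.call(rbind, lapply(y$loci, function(l)
    data.frame(id = l$id, chromosome = as.character(l$chromosome),
               position = l$position,
               recombFractionToNext =
                 if (is.null(l$recombFractionToNext)) NA_real_
                 else l$recombFractionToNext)))
  if (all(is.na(loci$recombFractionToNext))) loci$recombFractionToNext <- NULL
  killers <- lapply(y$killers, function(k) {
    if (!is.null(k$preset)) killerPreset(k$preset, id = k$id, locus = k$locus)
    else killerAllele(k$id, k$locus,
                      kappa = if (is.null(k$kappa)) 1 else k$kappa,
                      pi = if (is.null(k$pi)) 1 else k$pi,
                      resistanceSet = if (is.null(k$resistanceSet)) k$id
                                      else unlist(k$resistanceSet))
  })
  cfg <- crossConfig(loci, unlist(y$parent1), unlist(y$parent2),
                     killers = if (is.null(killers)) list() else killers)
  if (!is.null(y$chromosomes))
    attr(cfg, "chromLengths") <- unlist(y$chromosomes)
  cfg
}

#' Write a cross configuration file
#'
#' @param config A \linkS4class{CrossConfig}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCrossConfig <- function(config, path) {
  lo <- lociTable(config)
  y <- list(
    loci = lapply(seq_len(nrow(lo)), function(i)
      list(id = lo$id[i], chromosome = lo$chromosome[i],
           position = lo$position[i],
           recombFractionToNext = lo$recombFractionToNext[i])),
    parent1 = as.list(config@parent1),
    parent2 = as.list(config@parent2),
    killers = lapply(config@killers, function(k)
      list(id = k@id, locus = k@locus, kappa = k@kappa, pi = k@pi,
           resistanceSet = as.list(k@resistanceSet))))
  if (!is.null(attr(config, "chromLengths")))
    y$chromosomes <- as.list(attr(config, "chromLengths"))
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Write a synthetic gene family to FASTA + GFF3
#'
#' @param family Output of \code{\link{generateWtfFamily}}.
#' @param fastaPath,gffPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeFamilyFiles <- function(family, fastaPath, gffPath) {
  seqs <- Biostrings::DNAStringSet(family$sequences)
  Biostrings::writeXStringSet(seqs, fastaPath)
  fe <- family$features
  gffType <- ifelse(grepl("^exon", fe$type), "exon",
                    ifelse(fe$type == "LTR", "long_terminal_repeat",
                           ifelse(fe$type == "intron", "intron", "region")))
  lines <- sprintf("%s\twtfDrive\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   fe$gene, gffType, fe$start, fe$end, fe$strand,
                   paste0(fe$gene, ":", fe$type), fe$type)
  writeLines(c("##gff-version 3", lines), gffPath)
  invisible(c(fastaPath, gffPath))
}

#' Read gene models from a GFF3-like file
#'
#' Parses a GFF3 file whose exon features carry \code{ID=<gene>:exon<k>} (or
#' a \code{Parent=}) attribute, grouped per sequence region, as written by
#' \code{\link{writeFamilyFiles}}. Coordinates are 1-based inclusive,
#' gene-forward.
#'
#' @param path GFF3 path.
#' @return Named list of \linkS4class{GeneModel}.
#' @export
readGeneModelsGff <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t")
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stopf("malformed GFF line %d", bad[1])
  df <- data.frame(seqid = vapply(f, `[[`, "", 1),
                   type = vapply(f, `[[`, "", 3),
                   start = as.integer(vapply(f, `[[`, "", 4)),
                   end = as.integer(vapply(f, `[[`, "", 5)),
                   strand = vapply(f, `[[`, "", 7))
  ex <- df[df$type == "exon", , drop = FALSE]
  models <- lapply(split(ex, ex$seqid), function(g) {
    g <- g[order(g$start), ]
    geneModel(g$seqid[1], IRanges::IRanges(g$start, g$end),
              strand = g$strand[1])
  })
  models[unique(ex$seqid)]
}

#' Load the wtf gene-family inventory
#'
#' A plain-text inventory of the named wtf genes of the reference and
#' CBS5557 genomes with their published attributes: poison-isoform subtype
#' (intron-1-ATG vs exon-2-ATG carriers of the 150 bp element), membership
#' in the most-divergent set, and pseudogenizing lesion class.
#'
#' @return data.frame with columns \code{gene}, \code{genome},
#'   \code{subtype}, \code{divergent}, \code{lesion}.
#' @export
loadWtfInventory <- function() {
  read.delim(system.file("extdata", "wtf_gene_inventory.tsv",
                         package = "wtfDrive"), stringsAsFactors = FALSE)
}

#' Load the wtf family composition table
#'
#' Per-genome counts of wtf gene locations by multiplicity (singleton
#' locations, tandem-pair locations, triplet locations, plus genes at
#' locations absent from the other genome).
#'
#' @return data.frame with one row per genome.
#' @export
loadFamilyComposition <- function() {
  read.delim(system.file("extdata", "wtf_family_composition.tsv",
                         package = "wtfDrive"), stringsAsFactors = FALSE)
}

#' Gene-family composition arithmetic
#'
#' Derives per-genome and family-wide gene counts from the composition
#' table: genes per genome (singletons + 2 x pairs + 3 x triplets +
#' new-location genes) and the family total.
#'
#' @param composition Output of \code{\link{loadFamilyComposition}}.
#' @return data.frame with columns \code{genome} and \code{genes}, plus the
#'   family total as attribute \code{total}.
#' @export
familyCompositionCounts <- function(composition = loadFamilyComposition()) {
  genes <- composition$singleton_locations + 2 * composition$pair_locations +
    3 * composition$triplet_locations + composition$new_location_genes
  out <- data.frame(genome = composition$genome, genes = genes)
  attr(out, "total") <- sum(genes)
  out
}

#' Counts of poison-and-antidote subtypes in the inventory
#'
#' @param inventory Output of \code{\link{loadWtfInventory}}.
#' @return Named vector: \code{intron1_atg}, \code{exon2_atg},
#'   \code{motif_total}, \code{divergent}, \code{pseudogene}.
#' @export
motifGeneCounts <- function(inventory = loadWtfInventory()) {
  c(intron1_atg = sum(inventory$subtype == "intron1_atg"),
    exon2_atg = sum(inventory$subtype == "exon2_atg"),
    motif_total = sum(inventory$subtype %in% c("intron1_atg", "exon2_atg")),
    divergent = sum(inventory$divergent == 1),
    pseudogene = sum(inventory$lesion != "none"))
}
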