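# Command-line pipeline: subcommand dispatch, input validation, metadata
# sidecars. The exec/wtfdrive script is a thin wrapper around runPipeline().

.pkgVersion <- function()
  as.character(utils::packageVersion("wtfDrive"))

# parse "--flag value" style arguments into a named list
.parseArgs <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stopf("flag --%s needs a value", key)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

.argOr <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

.numArg <- function(opts, key, default) as.numeric(.argOr(opts, key, default))

# JSON metadata sidecar recording inputs, parameters, seed and version
.writeSidecar <- function(outPath, command, params) {
  meta <- list(command = command, parameters = params,
               version = .pkgVersion(),
               generated = "wtfDrive pipeline")
  jsonlite::write_json(meta, paste0(outPath, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Validate a pipeline input file
#'
#' Schema checks for the package's TSV inputs: required columns, types,
#' coordinate sanity (positive, sorted per chromosome), non-negative counts.
#' The first offending data line is reported.
#'
#' @param path File path.
#' @param schema One of \code{"counts"}, \code{"tetrads"}, \code{"synteny"}.
#' @return List with \code{ok} (logical) and \code{errors} (character,
#'   each prefixed with the 1-based data line number where applicable).
#' @export
validateInputs <- function(path, schema = c("counts", "tetrads", "synteny")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  errors <- character()
  addErr <- function(line, msg)
    errors[[length(errors) + 1L]] <<- if (is.na(line)) msg
      else sprintf("line %d: %s", line, msg)
  x <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                error = function(e) {
                  addErr(NA, conditionMessage(e)); NULL
                })
  if (!is.null(x)) {
    if (schema == "counts") {
      need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
      miss <- setdiff(need, names(x))
      if (length(miss)) {
        addErr(NA, paste("missing columns:", paste(miss, collapse = ", ")))
      } else {
        bad <- which(!is.finite(x$pos) | x$pos < 1)
        if (length(bad)) addErr(bad[1] + 1L, "position must be a positive integer")
        bad <- which(x$ref_count < 0 | x$alt_count < 0)
        if (length(bad)) addErr(bad[1] + 1L, "negative read count")
        for (chr in unique(x$chrom)) {
          ix <- which(x$chrom == chr)
          uns <- which(diff(x$pos[ix]) <= 0)
          if (length(uns))
            addErr(ix[uns[1] + 1L] + 1L,
                   sprintf("positions not strictly increasing on %s", chr))
        }
      }
    } else if (schema == "tetrads") {
      need <- c("cross_id", "tetrad_id", "spore_index", "viable")
      miss <- setdiff(need, names(x))
      if (length(miss)) {
        addErr(NA, paste("missing columns:", paste(miss, collapse = ", ")))
      } else {
        bad <- which(!x$spore_index %in% 1:4)
        if (length(bad)) addErr(bad[1] + 1L, "spore_index must be 1..4")
        bad <- which(!x$viable %in% 0:1)
        if (length(bad)) addErr(bad[1] + 1L, "viable must be 0 or 1")
        cnt <- table(paste(x$cross_id, x$tetrad_id))
        if (any(cnt != 4)) addErr(NA, "every tetrad needs exactly 4 spores")
      }
    } else if (schema == "synteny") {
      miss <- setdiff(c("gene", "group"), names(x))
      if (length(miss))
        addErr(NA, paste("missing columns:", paste(miss, collapse = ", ")))
      else if (anyDuplicated(x$gene))
        addErr(NA, "duplicate gene ids")
    }
  }
  list(ok = !length(errors), errors = errors)
}

# build the demo cross: two fully penetrant killers from the wild parent on
# opposite arms of a 2.4 Mb chromosome III analog
.demoCross <- function(chromLength = 2.4e6,
                       killerPositions = c(0.45e6, 1.8e6)) {
  loci <- data.frame(id = c("kL", "kR"), chromosome = "III",
                     position = killerPositions)
  cfg <- crossConfig(loci,
                     parent1 = c(kL = "+", kR = "+"),
                     parent2 = c(kL = "cwL", kR = "cwR"),
                     killers = list(killerAllele("cwL", "kL"),
                                    killerAllele("cwR", "kR")))
  attr(cfg, "chromLengths") <- c(III = chromLength)
  cfg
}

# individual subcommands -----------------------------------------------------

.cmdSimulateCross <- function(opts) {
  cfg <- readCrossConfig(opts$config)
  seed <- .numArg(opts, "seed", 1)
  n <- .numArg(opts, "n", 100)
  tt <- simulateMeiosisTetrads(cfg, n = n, seed = seed)
  writeTetradTable(tt, opts$out)
  .writeSidecar(opts$out, "simulate-cross",
                list(config = opts$config, n = n, seed = seed))
  opts$out
}

.cmdSimulatePool <- function(opts) {
  cfg <- readCrossConfig(opts$config)
  seed <- .numArg(opts, "seed", 1)
  colonies <- .numArg(opts, "colonies", 150)
  depth <- .numArg(opts, "depth", 15)
  density <- .numArg(opts, "snp-density", 25)
  chromLengths <- attr(cfg, "chromLengths")
  if (is.null(chromLengths)) {
    lo <- lociTable(cfg)
    chromLengths <- vapply(split(lo$position, lo$chromosome),
                           function(p) max(p) * 1.2, 0)
  }
  snp <- makeSnpMap(chromLengths, densityPer100kb = density, seed = seed)
  pool <- simulateViableSporePool(cfg, colonies, seed = seed + 1)
  counts <- simulatePoolReadcounts(pool, snp, meanDepth = depth,
                                   seed = seed + 2)
  writeCountTable(counts, opts$out)
  .writeSidecar(opts$out, "simulate-pool",
                list(config = opts$config, colonies = colonies, depth = depth,
                     snpDensity = density, seed = seed))
  opts$out
}

.cmdBsaScan <- function(opts) {
  counts <- readCountTable(opts$counts)
  minDepth <- .numArg(opts, "min-depth", 10)
  window <- .numArg(opts, "window", 45)
  delta <- .numArg(opts, "delta", 0.15)
  minRun <- .numArg(opts, "min-run", 45)
  track <- rollingMedianTrend(computeAlleleFrequencies(counts, minDepth),
                              window)
  regions <- detectDistortionRegions(track, delta = delta, minRun = minRun)
  prefix <- opts$out
  write.table(track, paste0(prefix, ".track.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(regions, paste0(prefix, ".regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeRegionsBed(regions, paste0(prefix, ".regions.bed"))
  .writeSidecar(prefix, "bsa-scan",
                list(counts = opts$counts, minDepth = minDepth,
                     window = window, delta = delta, minRun = minRun))
  message(sprintf("bsa-scan: %d SNPs kept (min depth %d), window %d, delta %g, min run %d; %d region(s)",
                  nrow(track), minDepth, window, delta, minRun, nrow(regions)))
  paste0(prefix, c(".track.tsv", ".regions.tsv", ".regions.bed"))
}

.cmdTetradTest <- function(opts) {
  tt <- readTetradTable(opts$tetrads)
  res <- genotypeRatioTest(tt, locus = opts$locus,
                           among = .argOr(opts, "among", "viable"))
  summ <- summarizeViability(tt)
  out <- list(viability = list(viable = summ$viable, total = summ$total,
                               fraction = summ$fraction),
              histogram = as.list(setNames(as.integer(summ$histogram),
                                           names(summ$histogram))),
              ratioTest = res)
  jsonlite::write_json(out, opts$out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  .writeSidecar(opts$out, "tetrad-test",
                list(tetrads = opts$tetrads, locus = opts$locus))
  opts$out
}

.cmdFitModel <- function(opts) {
  tt <- readTetradTable(opts$tetrads)
  cfg <- readCrossConfig(opts$config)
  fit <- fitKillerParameters(tt, cfg@killers)
  out <- list(estimates = fit$estimates, logLik = fit$logLik,
              convergence = fit$convergence)
  jsonlite::write_json(out, opts$out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  .writeSidecar(opts$out, "fit-model",
                list(tetrads = opts$tetrads, config = opts$config))
  opts$out
}

.cmdAnnotateGenes <- function(opts) {
  seqs <- Biostrings::readDNAStringSet(opts$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  models <- readGeneModelsGff(opts$gff)
  motifSeqs <- Biostrings::readDNAStringSet(opts$motifs)
  if (!all(c("conserved_up", "intron1_150bp") %in% names(motifSeqs)))
    stopf("motif FASTA must contain entries conserved_up and intron1_150bp")
  motifs <- list(
    conservedUp = motifDefinition("conserved_up",
                                  as.character(motifSeqs[["conserved_up"]]),
                                  expectedContext = "upstream"),
    intron1 = motifDefinition("intron1_150bp",
                              as.character(motifSeqs[["intron1_150bp"]]),
                              expectedContext = "intron1"))
  # family consensus from the annotated structures: modal exon count and
  # per-exon median lengths
  counts <- vapply(models, function(m) length(exonRanges(m)), 0L)
  consensusStructures <- lapply(sort(unique(counts)), function(k) {
    ms <- models[counts == k]
    lens <- sapply(ms, function(m) IRanges::width(exonRanges(m)))
    list(exonCount = k, exonLengths = apply(matrix(lens, nrow = k), 1, median))
  })
  names(consensusStructures) <- sort(unique(counts))
  fam <- list(sequences = setNames(as.character(seqs), names(seqs)),
              models = models, motifs = motifs,
              consensusStructures = consensusStructures, truth = NULL)
  res <- classifyFamily(fam,
                        exon2DepthLimit = .numArg(opts, "exon2-depth", 150))
  write.table(res, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeSidecar(opts$out, "annotate-genes",
                list(fasta = opts$fasta, gff = opts$gff,
                     motifs = opts$motifs))
  opts$out
}

.cmdPhyloNeighbors <- function(opts) {
  tree <- parseSupportedNewick(file = opts$tree)
  rooted <- midpointRoot(tree)
  minSupport <- .numArg(opts, "min-support", 95)
  pairs <- findNeighborPairs(rooted, minSupport = minSupport)
  prefix <- opts$out
  if (!is.null(opts$synteny)) {
    syn <- readSyntenyMap(opts$synteny)
    cls <- classifyPairsBySynteny(pairs, syn)
    pairs$syntenic <- c(rep(TRUE, nrow(cls$syntenic)),
                        rep(FALSE, nrow(cls$nonSyntenic)))[
      match(paste(pairs$leaf1, pairs$leaf2),
            c(paste(cls$syntenic$leaf1, cls$syntenic$leaf2),
              paste(cls$nonSyntenic$leaf1, cls$nonSyntenic$leaf2)))]
  }
  write.table(pairs, paste0(prefix, ".pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSupportedNewick(rooted, paste0(prefix, ".rooted.nwk"))
  .writeSidecar(prefix, "phylo-neighbors",
                list(tree = opts$tree, minSupport = minSupport,
                     synteny = opts$synteny))
  message(sprintf("phylo-neighbors: support cutoff %g, %d pair(s)",
                  minSupport, nrow(pairs)))
  paste0(prefix, c(".pairs.tsv", ".rooted.nwk"))
}

.cmdDemo <- function(opts) {
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  seed <- .numArg(opts, "seed", 1)
  cfg <- .demoCross()
  # two-peak transmission-distortion scan on pooled viable progeny
  snp <- makeSnpMap(attr(cfg, "chromLengths"), densityPer100kb = 125,
                    seed = seed)
  pool <- simulateViableSporePool(cfg, 150, seed = seed + 1)
  counts <- simulatePoolReadcounts(pool, snp, meanDepth = 15, seed = seed + 2)
  writeCountTable(counts, file.path(opts$out, "pool_counts.tsv"))
  track <- rollingMedianTrend(computeAlleleFrequencies(counts))
  regions <- detectDistortionRegions(track)
  write.table(regions, file.path(opts$out, "distortion_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # tetrad analysis of the same cross
  tt <- simulateMeiosisTetrads(cfg, n = 40, seed = seed + 3)
  writeTetradTable(tt, file.path(opts$out, "tetrads.tsv"))
  summ <- summarizeViability(tt)
  jsonlite::write_json(
    list(viability = summ$fraction,
         histogram = as.list(setNames(as.integer(summ$histogram),
                                      names(summ$histogram))),
         regions = nrow(regions), seed = seed),
    file.path(opts$out, "demo_summary.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  .writeSidecar(file.path(opts$out, "demo"), "demo", list(seed = seed))
  opts$out
}

#' Run a pipeline subcommand
#'
#' Subcommands: \code{simulate-cross}, \code{simulate-pool},
#' \code{bsa-scan}, \code{tetrad-test}, \code{fit-model},
#' \code{annotate-genes}, \code{phylo-neighbors}, \code{validate},
#' \code{demo}. Every output gains a JSON metadata sidecar recording the
#' command, parameters, seed and package version; on error, partial outputs
#' are removed.
#'
#' @param args Character vector: the subcommand followed by
#'   \code{--flag value} pairs (see the exec/wtfdrive script).
#' @return Invisibly, the paths written.
#' @export
runPipeline <- function(args) {
  if (!length(args)) stopf(paste(
    "usage: wtfdrive <subcommand> [--flag value ...]; subcommands:",
    "simulate-cross simulate-pool bsa-scan tetrad-test fit-model",
    "annotate-genes phylo-neighbors validate demo"))
  cmd <- args[1]
  opts <- .parseArgs(args[-1])
  run <- switch(cmd,
    "simulate-cross" = .cmdSimulateCross,
    "simulate-pool" = .cmdSimulatePool,
    "bsa-scan" = .cmdBsaScan,
    "tetrad-test" = .cmdTetradTest,
    "fit-model" = .cmdFitModel,
    "annotate-genes" = .cmdAnnotateGenes,
    "phylo-neighbors" = .cmdPhyloNeighbors,
    "demo" = .cmdDemo,
    "validate" = function(opts) {
      rep <- validateInputs(opts$path, opts$schema)
      if (!rep$ok) stopf("validation failed: %s",
                         paste(rep$errors, collapse = "; "))
      message("validation passed")
      character()
    },
    stopf("unknown subcommand '%s'", cmd))
  outputs <- character()
  tryCatch(
    outputs <- run(opts),
    error = function(e) {
      # remove partial outputs before failing
      toClean <- unlist(lapply(opts[c("out")], function(p)
        if (!is.null(p) && file.exists(p) && !dir.exists(p)) p))
      if (length(toClean)) unlink(toClean)
      stop(e)
    })
  invisible(outputs)
}
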