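# Motif scanning, start-codon subtyping, pseudogene calling, identity,
# LTR-deletion detection.

test_that("motif scanning finds planted elements and rejects noise", {
  set.seed(401)
  motifSeq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                    collapse = "")
  motif <- motifDefinition("intron1_150bp", motifSeq,
                          expectedContext = "intron1")
  randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  # exact plant
  seq <- paste0(randSeq(200), motifSeq, randSeq(150))
  hits <- scanMotif(seq, motif)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 201)
  expect_equal(hits$identity, 1.0)

  # 10% substitutions: hit near identity 0.9
  ch <- strsplit(motifSeq, "")[[1]]
  mut <- sample(150, 15)
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  seqMut <- paste0(randSeq(100), paste(ch, collapse = ""), randSeq(100))
  hits <- scanMotif(seqMut, motif)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 0.9)

  # random sequences: no false hits at the 0.8 threshold
  for (i in 1:100) expect_equal(nrow(scanMotif(randSeq(400), motif)), 0)
  expect_error(scanMotif(randSeq(100), motif), "shorter")
})

test_that("first in-frame ATG location distinguishes the subtypes", {
  fam <- generateWtfFamily(list(
    syntheticGenePlan("gi", hasIntron1Motif = TRUE, plantedAtg = "intron1",
                      atgOffset = 7),
    syntheticGenePlan("ge", hasIntron1Motif = TRUE, plantedAtg = "exon2",
                      atgOffset = 30),
    syntheticGenePlan("ga")), seed = 42)

  gi <- fam$models[["gi"]]
  intron1Start <- IRanges::end(exonRanges(gi))[1] + 1L
  res <- locateFirstInframeAtg(gi, fam$sequences[["gi"]], intron1Start)
  expect_equal(res$location, "intron1")
  expect_equal(res$distanceToExon2, 7)

  ge <- fam$models[["ge"]]
  res <- locateFirstInframeAtg(ge, fam$sequences[["ge"]],
                               IRanges::end(exonRanges(ge))[1] + 1L)
  expect_equal(res$location, "exon2")
  e2 <- IRanges::start(exonRanges(ge))[2]
  expect_equal(res$position, e2 + 30)

  ga <- fam$models[["ga"]]
  res <- locateFirstInframeAtg(ga, fam$sequences[["ga"]],
                               IRanges::end(exonRanges(ga))[1] + 1L)
  expect_equal(res$location, "none")

  expect_error(
    locateFirstInframeAtg(gi, fam$sequences[["gi"]],
                          IRanges::start(exonRanges(gi))[2] + 5L),
    "beyond")

  # out-of-frame intron ATGs are skipped: exon1 is 6 bp, so an in-frame
  # intron ATG needs (distance to exon 2) %% 3 == 0; the ATGs at positions
  # 10 and 14 sit at distances 8 and 4 and must be passed over in favor of
  # the codon-aligned ATG at the start of exon 2 (position 21)
  seq <- "ATGCCCGTAATGCATGAAAGATGTAA"
  gm <- geneModel("toy", cbind(c(1, 21), c(6, 26)))
  res <- locateFirstInframeAtg(gm, seq, 7)
  expect_equal(res$location, "exon2")
  expect_equal(res$position, 21)
})

test_that("pseudogene lesions are called by class", {
  plans <- list(
    syntheticGenePlan("ok"),
    syntheticGenePlan("ls", plantedLesion = "lost_start"),
    syntheticGenePlan("ps", plantedLesion = "premature_stop"),
    syntheticGenePlan("fs", plantedLesion = "frameshift_indel"),
    syntheticGenePlan("sd", plantedLesion = "segmental_deletion"),
    syntheticGenePlan("sd5", exonCount = 5,
                      plantedLesion = "segmental_deletion"))
  fam <- generateWtfFamily(plans, seed = 77)
  lesionOf <- function(id) {
    cons <- fam$consensusStructures[[as.character(
      fam$truth$exonCount[fam$truth$geneId == id])]]
    callPseudogene(fam$models[[id]], fam$sequences[[id]], cons)
  }
  expect_equal(lesionOf("ok"), character(0))
  expect_equal(lesionOf("ls"), "lost_start")
  expect_equal(lesionOf("ps"), "premature_stop")
  expect_equal(lesionOf("fs"), "frameshift_indel")
  expect_equal(lesionOf("sd"), "segmental_deletion")
  expect_equal(lesionOf("sd5"), "segmental_deletion")
})

test_that("gene classification follows the precedence rules", {
  plans <- list(
    syntheticGenePlan("pa1", hasIntron1Motif = TRUE, plantedAtg = "intron1",
                      atgOffset = 7),
    syntheticGenePlan("pa2", hasIntron1Motif = TRUE, plantedAtg = "exon2",
                      atgOffset = 30),
    syntheticGenePlan("ao"),
    syntheticGenePlan("pg", hasIntron1Motif = TRUE, plantedAtg = "intron1",
                      plantedLesion = "premature_stop"),
    syntheticGenePlan("dv"))
  fam <- generateWtfFamily(plans, seed = 88)
  res <- classifyFamily(fam, divergentList = "dv")
  got <- setNames(res$category, res$geneId)
  expect_equal(unname(got["pa1"]), "poison_and_antidote_intron1_atg")
  expect_equal(unname(got["pa2"]), "poison_and_antidote_exon2_atg")
  expect_equal(unname(got["ao"]), "antidote_only")
  expect_equal(unname(got["pg"]), "pseudogene")  # lesions take precedence
  expect_equal(unname(got["dv"]), "divergent_unclassified")
  expect_equal(res$atgDistanceToExon2[res$geneId == "pa1"], 7)
})

test_that("pairwise identity handles gaps per the alignment-length rule", {
  expect_equal(pairwiseIdentity(strrep("ACGT", 25), strrep("ACGT", 25)), 1.0)
  expect_equal(pairwiseIdentity("ACGT-A", "ACGTTA"), 5 / 6)
  expect_equal(pairwiseIdentity("AC--GT", "AC--GT"), 1.0)  # both-gap removed
  expect_equal(pairwiseIdentity("ACGT-A", "ACGTTA"),
               pairwiseIdentity("ACGTTA", "ACGT-A"))
  expect_lt(pairwiseIdentity("AAAA", "AAAT"), 1)
  expect_error(pairwiseIdentity("AAA", "AAAA"), "equal length")
})

test_that("LTR-mediated deletions are reconstructed exactly", {
  fam <- generateWtfFamily(list(
    syntheticGenePlan("g", ltrFlanks = "directly_oriented_pair")),
    seed = 99, ltrHomology = 7)
  rec <- applyLtrRecombination(fam, "g")
  ltrs <- fam$features[fam$features$gene == "g" &
                       fam$features$type == "LTR", ]
  det <- detectLtrDeletion(
    fam$sequences[["g"]], ltrs, rec$sequence,
    data.frame(start = rec$ltr["start"], end = rec$ltr["end"], strand = "+"))
  expect_true(det$detected)
  expect_equal(det$deletedStart, rec$deletedStart)
  expect_equal(det$deletedEnd, rec$deletedEnd)
  expect_equal(det$homologyLength, 7)

  # inverted orientation: no event
  inv <- ltrs; inv$strand <- c("+", "-")
  det <- detectLtrDeletion(fam$sequences[["g"]], inv, rec$sequence,
                           data.frame(start = rec$ltr["start"],
                                      end = rec$ltr["end"], strand = "+"))
  expect_false(det$detected)
  expect_match(det$reason, "inverted")

  # an unrelated LTR is rejected
  other <- generateWtfFamily(list(
    syntheticGenePlan("h", ltrFlanks = "single")), seed = 123)
  hLtr <- other$features[other$features$gene == "h" &
                         other$features$type == "LTR", ]
  det <- detectLtrDeletion(fam$sequences[["g"]], ltrs,
                           other$sequences[["h"]], hLtr)
  expect_false(det$detected)
})
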