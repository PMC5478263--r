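# Tree parsing, midpoint rooting, cherry detection, synteny classification.
# (bruteMidpointHeight lives in helper-oracles.R)

test_that("newick parsing and writing round-trip supports and lengths", {
  st <- parseSupportedNewick("((A:1,B:2)97:0.5,C:3);")
  tr <- apeTree(st)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  pairs <- findNeighborPairs(st)
  expect_equal(pairs$leaf1, "A")
  expect_equal(pairs$support, 97)

  # empty support labels are recorded as missing
  st2 <- parseSupportedNewick("((A:1,B:2):0.5,C:3);")
  expect_true(all(is.na(nodeSupports(st2)) |
                  nodeSupports(st2) == nodeSupports(st2)))

  # round-trip on a random 50-leaf tree with supports
  set.seed(501)
  tr <- ape::rtree(50)
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  txt <- ape::write.tree(tr)
  st3 <- parseSupportedNewick(txt)
  expect_equal(writeSupportedNewick(st3), txt)
  back <- apeTree(st3)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_equal(back$node.label, tr$node.label)

  expect_error(parseSupportedNewick("((A:1,B:2"), "malformed")
})

test_that("midpoint rooting places the root halfway along the diameter", {
  # closed form: (A:1,B:5) roots 3 from each
  rt <- midpointRoot(parseSupportedNewick("(A:1,B:5);"))
  D <- ape::dist.nodes(apeTree(rt))
  expect_equal(unname(D[1:2, 3]), c(3, 3), tolerance = 1e-9)

  # random trees match the brute-force edge search
  set.seed(502)
  for (i in 1:10) {
    tr <- ape::rtree(20)
    st <- new("SupportedTree", tree = tr)
    rt <- apeTree(midpointRoot(st))
    n <- 20
    D <- ape::dist.nodes(rt)
    root <- n + 1
    expect_equal(max(D[seq_len(n), root]), bruteMidpointHeight(tr),
                 tolerance = 1e-9)
    # the two endpoints of the longest path are equidistant from the root
    dT <- D[seq_len(n), seq_len(n)]
    ij <- which(dT == max(dT), arr.ind = TRUE)[1, ]
    expect_lt(abs(D[ij[1], root] - D[ij[2], root]), 1e-9)
    # leaf-to-leaf path lengths are preserved
    d0 <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
    dimnames(d0) <- list(tr$tip.label, tr$tip.label)
    d1 <- dT
    dimnames(d1) <- list(rt$tip.label, rt$tip.label)
    expect_equal(d1[tr$tip.label, tr$tip.label], d0, tolerance = 1e-9)
  }

  # ties resolve deterministically (both runs identical)
  tie <- "(A:2,(B:1,C:1):1);"
  r1 <- writeSupportedNewick(midpointRoot(parseSupportedNewick(tie)))
  r2 <- writeSupportedNewick(midpointRoot(parseSupportedNewick(tie)))
  expect_identical(r1, r2)

  expect_error(midpointRoot(parseSupportedNewick("(A:0,B:0);")),
               "midpoint undefined")
})

test_that("cherry detection returns exactly the high-support sister pairs", {
  st <- parseSupportedNewick("((A:1,B:1)97:1,(C:1,D:1)80:1);")
  pairs <- findNeighborPairs(st)
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$leaf1, pairs$leaf2), c("A", "B"))

  # star tree: no cherries
  star <- parseSupportedNewick("(A:1,B:1,C:1,D:1);")
  expect_equal(nrow(findNeighborPairs(star)), 0)

  # planted cherries on a simulated backbone are recovered exactly
  planted <- list(c("p1", "q1"), c("p2", "q2"), c("p3", "q3"), c("p4", "q4"))
  st <- simulateSupportedTree(12, cherries = planted, seed = 7)
  pairs <- findNeighborPairs(midpointRoot(st))
  expect_equal(nrow(pairs), 4)
  got <- apply(pairs[, 1:2], 1, paste, collapse = "|")
  want <- vapply(planted, function(p) paste(sort(p), collapse = "|"), "")
  expect_setequal(got, want)

  # a cherry with no support is excluded with a warning
  st <- parseSupportedNewick("((A:1,B:1):1,(C:1,D:1)99:1);")
  expect_warning(pairs <- findNeighborPairs(st), "no support")
  expect_equal(c(pairs$leaf1, pairs$leaf2), c("C", "D"))
})

test_that("cherries are invariant under re-rooting outside them", {
  planted <- list(c("p1", "q1"), c("p2", "q2"))
  st <- simulateSupportedTree(10, cherries = planted, seed = 9)
  p0 <- findNeighborPairs(st)
  rooted <- midpointRoot(st)
  p1 <- findNeighborPairs(rooted)
  tr <- apeTree(st)
  outgroup <- grep("^bb", tr$tip.label, value = TRUE)[1]
  tr2 <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  p2 <- findNeighborPairs(new("SupportedTree", tree = tr2))
  expect_equal(p1[, 1:2], p0[, 1:2])
  expect_equal(p2[, 1:2], p0[, 1:2])
})

test_that("synteny classification separates orthologous pairs", {
  syn <- data.frame(
    gene = c("cw9", "wtf9", "cw27", "wtf13", "cw4", "wtf4"),
    group = c("9", "9", "g27", "13", "4", "4"),
    genome = c("CBS5557", "reference", "CBS5557", "reference",
               "CBS5557", "reference"))
  pairs <- data.frame(leaf1 = c("cw9", "cw27", "cw4"),
                      leaf2 = c("wtf9", "wtf13", "wtf4"),
                      support = c(99, 98, 97))
  cls <- classifyPairsBySynteny(pairs, syn)
  expect_equal(unname(cls$counts), c(3, 2, 1))
  expect_setequal(cls$syntenic$leaf1, c("cw9", "cw4"))
  expect_equal(cls$nonSyntenic$leaf1, "cw27")
  expect_equal(sum(cls$counts[c("syntenic", "nonSyntenic")]),
               unname(cls$counts["total"]))

  # same-genome pairs are non-syntenic even within a group
  sameGenome <- data.frame(leaf1 = "cw4", leaf2 = "cw9", support = 99)
  syn2 <- rbind(syn, data.frame(gene = "cw4b", group = "4",
                                genome = "CBS5557"))
  cls2 <- classifyPairsBySynteny(
    data.frame(leaf1 = "cw4", leaf2 = "cw4b", support = 99), syn2)
  expect_equal(unname(cls2$counts["syntenic"]), 0L)

  expect_error(
    classifyPairsBySynteny(data.frame(leaf1 = "x", leaf2 = "x",
                                      support = 99), syn),
    "same leaf")
  expect_error(
    classifyPairsBySynteny(data.frame(leaf1 = "nope", leaf2 = "cw9",
                                      support = 99), syn),
    "missing")
})
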