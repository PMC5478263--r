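# Support-labeled trees: parsing, midpoint rooting with support values
# attached to bipartitions, cherry (phylogenetic neighbor) detection, and
# synteny classification of neighbor pairs.

#' Parse a newick tree with support labels
#'
#' Internal node labels are interpreted as bootstrap-style support values
#' (commonly ultrafast-bootstrap percentages); empty labels are recorded as
#' missing support.
#'
#' @param text Newick string, or \code{file} a path.
#' @param file Optional path to a newick file.
#' @return A \linkS4class{SupportedTree}.
#' @examples
#' parseSupportedNewick("((A:1,B:2)97:0.5,C:3);")
#' @export
parseSupportedNewick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stopf("malformed newick: %s", conditionMessage(e)),
    warning = function(w) stopf("malformed newick: %s", conditionMessage(w)))
  if (is.null(tr)) stopf("malformed newick: could not parse input")
  new("SupportedTree", tree = tr)
}

#' Write a SupportedTree as newick
#'
#' @param x A \linkS4class{SupportedTree}.
#' @param file Output path; when NULL, the newick string is returned.
#' @return The path (or the newick string), invisibly.
#' @export
writeSupportedNewick <- function(x, file = NULL) {
  tr <- apeTree(x)
  if (is.null(file)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = file)
  invisible(file)
}

# canonical key for the bipartition induced by an internal node: the tip-set
# on the side NOT containing the alphabetically first tip label, sorted and
# pasted. Keys are invariant under re-rooting.
.splitKeys <- function(tr) {
  nTip <- length(tr$tip.label)
  ref <- sort(tr$tip.label)[1]
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  vapply(seq_along(parts), function(i) {
    tips <- labs[parts[[i]]]
    if (ref %in% tips) tips <- setdiff(labs, tips)
    paste(sort(tips), collapse = "|")
  }, "")
}

#' Midpoint rooting
#'
#' Roots the tree at the midpoint of the longest leaf-to-leaf path, so the
#' two endpoints of that path are equidistant from the root. Ties between
#' equally long paths are broken deterministically by the lexicographically
#' smallest sorted endpoint label pair. Support values follow their
#' bipartitions through the re-rooting.
#'
#' @param x A \linkS4class{SupportedTree} (or \code{phylo}).
#' @return A rooted \linkS4class{SupportedTree}.
#' @export
midpointRoot <- function(x) {
  tr <- if (is(x, "SupportedTree")) apeTree(x) else x
  nTip <- length(tr$tip.label)
  if (nTip < 2) stopf("midpoint rooting needs at least 2 leaves")
  if (is.null(tr$edge.length) || all(tr$edge.length <= 0))
    stopf("midpoint undefined: tree has no positive branch lengths")

  # support values keyed by bipartition, restored after re-rooting
  supKey <- NULL
  if (!is.null(tr$node.label)) {
    keys <- .splitKeys(tr)
    supKey <- setNames(tr$node.label, keys)
    supKey <- supKey[nzchar(names(supKey))]
    tr$node.label <- NULL
  }

  D <- ape::dist.nodes(tr)
  dTips <- D[seq_len(nTip), seq_len(nTip)]
  mx <- max(dTips)
  hits <- which(dTips >= mx - 1e-12 & upper.tri(dTips), arr.ind = TRUE)
  pairLab <- apply(hits, 1, function(ij)
    paste(sort(tr$tip.label[ij]), collapse = "\r"))
  pick <- hits[order(pairLab)[1], ]
  i <- pick[1]; j <- pick[2]

  path <- ape::nodepath(tr, i, j)
  cum <- D[i, path]
  half <- D[i, j] / 2
  k <- max(which(cum <= half + 1e-12))
  if (abs(cum[k] - half) < 1e-12 && k > 1 && k < length(path)) {
    # midpoint falls exactly on an internal node: root on the following edge
    # at position 0 from that node
    a <- path[k]; b <- path[k + 1]
  } else {
    a <- path[k]; b <- path[k + 1]
  }
  # phytools::reroot places the root along the edge above `node`, with
  # `position` measured from the parent end of that edge; find which of a,b
  # is the child
  childIsB <- any(tr$edge[, 1] == a & tr$edge[, 2] == b)
  if (childIsB) {
    child <- b; pos <- half - cum[k]       # distance from parent a
  } else {
    child <- a; pos <- cum[k + 1] - half   # distance from parent b
  }
  rooted <- phytools::reroot(tr, child, position = pos)
  rooted$node.label <- NULL

  if (!is.null(supKey)) {
    keys <- .splitKeys(rooted)
    lab <- unname(supKey[keys])
    lab[is.na(lab)] <- ""
    rooted$node.label <- lab
  }
  new("SupportedTree", tree = rooted)
}

#' Find phylogenetic-neighbor pairs
#'
#' Two leaves are phylogenetic neighbors when they are separated by a single
#' internal node (they form a cherry) whose support value reaches the
#' threshold. Cherries without a support value are excluded with a warning.
#'
#' @param x A rooted \linkS4class{SupportedTree}.
#' @param minSupport Minimum support (default 95).
#' @return data.frame with columns \code{leaf1}, \code{leaf2},
#'   \code{support}, sorted lexicographically; zero rows when there are no
#'   qualifying cherries.
#' @export
findNeighborPairs <- function(x, minSupport = 95) {
  tr <- apeTree(x)
  nTip <- length(tr$tip.label)
  sup <- nodeSupports(x)
  out <- list()
  for (nd in nTip + seq_len(tr$Nnode)) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    if (length(kids) != 2L || any(kids > nTip)) next
    s <- sup[nd - nTip]
    if (is.na(s)) {
      warnf("cherry (%s, %s) has no support value; excluded",
            tr$tip.label[kids[1]], tr$tip.label[kids[2]])
      next
    }
    if (s >= minSupport) {
      lab <- sort(tr$tip.label[kids])
      out[[length(out) + 1L]] <- data.frame(leaf1 = lab[1], leaf2 = lab[2],
                                            support = s)
    }
  }
  if (!length(out))
    return(data.frame(leaf1 = character(), leaf2 = character(),
                      support = numeric()))
  out <- do.call(rbind, out)
  out <- out[order(out$leaf1, out$leaf2), ]
  rownames(out) <- NULL
  out
}

#' Classify neighbor pairs by synteny
#'
#' A pair is syntenic when both members belong to the same syntenic group
#' and come from different genomes; pairs from the same genome are
#' non-syntenic by definition.
#'
#' @param pairs data.frame from \code{\link{findNeighborPairs}}.
#' @param synteny data.frame with columns \code{gene}, \code{group},
#'   \code{genome} (see \code{\link{readSyntenyMap}}).
#' @return List with \code{syntenic}, \code{nonSyntenic} (subsets of
#'   \code{pairs}) and \code{counts} (named vector: total, syntenic,
#'   nonSyntenic).
#' @export
classifyPairsBySynteny <- function(pairs, synteny) {
  if (nrow(pairs) && any(pairs$leaf1 == pairs$leaf2))
    stopf("a pair cannot contain the same leaf twice")
  missing <- setdiff(c(pairs$leaf1, pairs$leaf2), synteny$gene)
  if (length(missing))
    stopf("genes missing from synteny map: %s", paste(missing, collapse = ", "))
  idx1 <- match(pairs$leaf1, synteny$gene)
  idx2 <- match(pairs$leaf2, synteny$gene)
  isSyn <- synteny$group[idx1] == synteny$group[idx2] &
    synteny$genome[idx1] != synteny$genome[idx2]
  if (!nrow(pairs)) isSyn <- logical()
  list(syntenic = pairs[isSyn, , drop = FALSE],
       nonSyntenic = pairs[!isSyn, , drop = FALSE],
       counts = c(total = nrow(pairs), syntenic = sum(isSyn),
                  nonSyntenic = sum(!isSyn)))
}

#' Simulate a support-labeled tree with planted cherries
#'
#' Generates a random backbone tree and grafts the requested leaf pairs onto
#' random backbone edges as cherries with high support; all other internal
#' nodes get supports drawn below the planting threshold. Used to exercise
#' neighbor detection with known ground truth.
#'
#' @param nBackbone Number of backbone leaves (named bb1, bb2, ...).
#' @param cherries List of character vectors of length 2: the leaf pairs to
#'   plant.
#' @param seed Integer seed.
#' @param cherrySupport Support assigned to planted cherries.
#' @param maxOtherSupport Upper bound for all other supports.
#' @return A \linkS4class{SupportedTree}.
#' @export
simulateSupportedTree <- function(nBackbone, cherries = list(), seed = 1,
                                  cherrySupport = 99, maxOtherSupport = 90) {
  withSeed(seed, {
    tr <- ape::rtree(nBackbone, tip.label = paste0("bb", seq_len(nBackbone)))
    for (pr in cherries) {
      # graft the pair as a subtree onto a random backbone tip edge; the
      # pair's own root node keeps it a cherry
      host <- sample(grep("^bb", tr$tip.label), 1)
      sub <- ape::read.tree(text = sprintf("(%s:%.4f,%s:%.4f):0.05;", pr[1],
                                           runif(1, 0.05, 0.2), pr[2],
                                           runif(1, 0.05, 0.2)))
      tr <- ape::bind.tree(tr, sub, where = host,
                           position = tr$edge.length[tr$edge[, 2] == host] / 2)
    }
    # assign supports: planted cherries high, everything else below threshold
    nTip <- length(tr$tip.label)
    lab <- as.character(round(runif(tr$Nnode, 40, maxOtherSupport)))
    plantedKeys <- vapply(cherries, function(pr)
      paste(sort(pr), collapse = "|"), "")
    for (nd in nTip + seq_len(tr$Nnode)) {
      kids <- tr$edge[tr$edge[, 1] == nd, 2]
      if (length(kids) == 2L && all(kids <= nTip)) {
        key <- paste(sort(tr$tip.label[kids]), collapse = "|")
        lab[nd - nTip] <- if (key %in% plantedKeys)
          as.character(cherrySupport) else as.character(round(runif(1, 40, maxOtherSupport)))
      }
    }
    tr$node.label <- lab
    new("SupportedTree", tree = tr)
  })
}
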