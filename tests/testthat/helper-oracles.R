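# Independent oracles shared across tests.

# closed-form brute force for midpoint rooting: for every edge, the optimal
# root position minimizing the maximum root-to-leaf distance
bruteMidpointHeight <- function(tr) {
  n <- length(tr$tip.label)
  D <- ape::dist.nodes(tr)
  best <- Inf
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; L <- tr$edge.length[e]
    # leaves reached through the child side vs the parent side
    viaChild <- D[seq_len(n), ch] + L < D[seq_len(n), p] + 1e-12
    A <- max(D[which(viaChild), ch], -Inf)
    B <- max(D[setdiff(seq_len(n), which(viaChild)), p], -Inf)
    x <- min(max((B + L - A) / 2, 0), L)
    best <- min(best, max(A + x, B + L - x))
  }
  best
}
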