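# Shared helpers: map functions, RNG scoping, run-length utilities.

#' Haldane map function
#'
#' Convert a physical distance to a recombination fraction assuming crossovers
#' occur as a Poisson process with no interference (Haldane).
#'
#' @param distanceBp Numeric vector of physical distances in base pairs.
#' @param cMPerKb Recombination rate in centimorgans per kilobase. The default
#'   0.16 cM/kb is a genome-average figure for fission yeast.
#' @return Recombination fractions in \code{[0, 0.5)}.
#' @examples
#' haldaneFraction(c(0, 1e5, 1e7))
#' @export
haldaneFraction <- function(distanceBp, cMPerKb = 0.16) {
  stopifnot(all(distanceBp >= 0), cMPerKb >= 0)
  morgans <- distanceBp / 1000 * cMPerKb / 100
  0.5 * (1 - exp(-2 * morgans))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulators never perturb user code.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Maximal runs of TRUE in a logical vector, as a data.frame(start, end) of
# indices; runs shorter than minLen are dropped. NA counts as FALSE.
trueRuns <- function(x, minLen = 1L) {
  x <- !is.na(x) & x
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  data.frame(start = starts[keep], end = ends[keep])
}

# stop() with a message assembled via sprintf, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
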