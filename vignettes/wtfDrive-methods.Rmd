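---
title: "wtfDrive: models and methods"
author: "wtfDrive authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wtfDrive: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtfDrive)
```

# The poison–antidote model

*wtf*-family spore killers act after meiosis in fission yeast: a killer
allele present in the diploid expresses a trans-acting poison that reaches
all four spores of the ascus, and a cis-restricted antidote that rescues
only the spores inheriting the allele. `wtfDrive` abstracts each killer
allele into three quantities:

* **killing penetrance** `kappa` ∈ [0, 1] — the probability that a spore
  exposed to the poison and not protected against it dies;
* **antidote efficiency** `pi` ∈ [0, 1] — the probability that a spore
  carrying the allele is protected against a poison in its resistance set;
* **resistance set** — the poisons this allele's antidote neutralizes; by
  default only the allele's own poison. Two active killers with disjoint
  resistance sets therefore kill mutually: a spore inheriting only one of
  them is killed by the other, and a cross of two strains carrying
  different killers at the same locus leaves essentially no survivors.

A spore with genotype *g* survives with probability

$$S(g) \;=\; \prod_k \bigl[\,1 - \kappa_k\,(1 - \mathrm{prot}_k(g))\,\bigr],
\qquad
\mathrm{prot}_k(g) = \max_{a \in g,\; k \in R(a)} \pi_a \;\;(\text{else } 0).$$

Killers act multiplicatively and independently; this is the minimal model
that reproduces all the qualitative outcomes observed for this gene family
(heterozygous-only killing, normal viability in homozygous crosses, mutual
killing without cross-resistance, and the separability of killing and
protection seen in truncation series). The `killerPreset()` bundles encode
that truncation phenomenology: `Ta`/`Tc` are fully active (κ = 1, π = 1),
`Td` has lost killing but protects (κ = 0, π = 1), and `Tb`/`Te` have
partially lost protection. The truncation data order the protection loss
(`Te` worse than `Tb`) but do not quantify it; the preset values π = 0.75
(`Tb`) and π = 0.5 (`Te`) are representative choices on that ordering, not
measured quantities, and should be treated as placeholders when fitting
real data.

## Tetrad semantics and recombination

Expectations (`tetradOutcomeDistribution`, `expectedViability`,
`expectedViableAlleleFrequency`) are computed by exact enumeration of
tetrad segregation patterns:

* every locus segregates 2:2 within a tetrad (no gene conversion);
* for each interval between adjacent linked loci the tetrad either keeps
  its arrangement (probability 1 − 2r) or exchanges the parental origins of
  one currently-parent-1 spore and one currently-parent-2 spore
  (probability 2r, uniform over choices), which preserves 2:2 at every
  locus and gives each spore the marginal recombination fraction r;
* loci on different chromosomes assort independently.

This is a simplification of four-strand meiosis (no distinct
non-parental-ditype class, no chromatid or crossover interference); it is
exact for the marginal quantities the package reports — per-spore genotype
frequencies and survival — which is what viability and pooled-frequency
expectations need. Recombination fractions may be supplied directly (e.g.
r = 0 for same-locus repulsion constructs) or derived from physical
distance with the Haldane map function at a genome-average rate of
0.16 cM/kb, a standard figure for fission yeast.

Pooled allele frequencies are defined as the ratio of expectations
E[viable carriers]/E[viable spores], the large-pool limit of a
random-spore-analysis pool; for a heterozygous killer with penetrance κ the
non-carrier frequency among survivors is (1 − κ)/(2 − κ).

## Maximum-likelihood fitting

`fitKillerParameters()` maximizes the Bernoulli likelihood of per-spore
viability over (κ, π) per killer. The optimizer is deliberately
deterministic: an exhaustive grid at step 0.05 followed by box-constrained
BFGS refinement, so a fit is a pure function of the data. Estimates on the
[0, 1] boundary are reported as-is and flagged; parameters that the data
cannot inform are flagged per parameter (κ needs exposed unprotected
spores, π needs carriers) rather than silently returned. On simulated data
the fit coincides with the closed-form MLE; note that at low κ the
antidote efficiency is weakly identified — with 500 tetrads the sampling
standard deviation of the π estimate at κ = 0.25 is about 0.05 — so
recovery tolerances tighter than ~2 SD will occasionally fail by honest
sampling noise.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study's data at reduced
scale, with exact ground truth:

* `makeSnpMap()` places SNPs at 25/100 kb by default — the genome of a
  divergent isolate pair carries several SNPs per kb, and the package's
  simulations run at roughly one-tenth that density to keep test runtimes
  in seconds; density is a parameter, not a constraint.
* `simulateMeiosisTetrads()` samples the same process the enumeration
  integrates, so simulator and analytics agree by construction up to
  sampling error (tested at 3 standard errors).
* `simulateViableSporePool()` + `simulatePoolReadcounts()` emulate pooling
  ≥150 viable colonies and sequencing at ~15× mean depth: depth is
  Poisson (only mean depths are known for the real data), reference counts
  are binomial in the pool frequency, and the per-base error rate defaults
  to 0 because base- and mapping-quality filtering is assumed upstream of
  the count table.
* `generateWtfFamily()` builds gene regions from template structures
  (5 or 6 exons; exon lengths 240/147/120/162/[201]/99 adjusted ±2 bp for
  reading-frame constraints) and plants the family's sequence features:
  a 288 bp conserved upstream element, a 150 bp intron-1 element, an
  in-frame poison-isoform ATG either in intron 1 (default 7 bp upstream of
  exon 2) or in exon 2, each pseudogenizing lesion class, and single or
  directly oriented LTR flanks with a plantable perfect homology window at
  the recombination junction. Divergence is applied as uniform random
  substitutions restricted to regions that cannot alter the planted truth
  (the generator also sanitizes the ATG scan window), so classification
  tests measure the classifier, not generator noise.

Not emulated: read-level artifacts (mapping bias, duplicates), aneuploidy,
gene conversion within tetrads, selection on colony formation beyond
viability, and indel evolution outside planted lesions. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms under
the stated model, not robustness to alignment artifacts in real pools.

# The bulk-segregant scan

* **Depth filter**: SNPs with fewer than 10 combined reference+variant
  reads are dropped (7 is the conventional relaxation for low-coverage
  pools). Frequencies are ref/(ref+var); the filter subsumes the
  division-by-zero case.
* **Trend**: a centered rolling median over 45 consecutive SNPs, computed
  per chromosome (via `zoo`). The trend is undefined where no full window
  fits — the first and last 22 SNPs of a chromosome — because partial
  windows would bias the edges; chromosomes shorter than the window get no
  trend and a warning.
* **Region calling** (`detectDistortionRegions`): runs of SNPs whose trend
  deviates from 0.5 by more than `delta = 0.15`, merged across
  sub-threshold interruptions shorter than `mergeGap` (default `minRun`)
  SNPs, and kept when they carry at least `minRun = 45` deviating SNPs.
  The merge rule exists because at 15× depth the rolling median inside a
  broad distortion valley occasionally pops back over the threshold for a
  handful of SNPs; an interruption shorter than the evidence threshold is
  not evidence of two separate regions. The thresholds are this package's
  peak-calling rule (the original analyses read peaks from plots); both
  are exposed as function and CLI parameters. Defaults were chosen so that
  fully penetrant killers at ~15× depth and ~125 SNPs/100 kb are called as
  single clean regions; with two linked killers on one chromosome the
  whole chromosome is genuinely distorted and a weak middle region near
  the threshold can appear — raising `delta` separates the two deep
  valleys sharply.
* **Donor segments** (`inferDonorSegments`): runs of ≥20 SNPs at reference
  frequency ≤ 0.95, with the same gap-merge logic (a single SNP sampled at
  full reference frequency inside a 900-SNP segregating segment must not
  split it; true inter-segment gaps sit at frequency ≈ 1 for hundreds of
  SNPs and are never bridged). Segment bounds are the first/last
  qualifying SNP, so boundary error is at most one inter-SNP gap.
* **Coordinates** are 1-based inclusive throughout; BED export converts to
  0-based half-open.

# Exact tetrad statistics

Both `fisherExact2x2()` and `exactBinomialTwoSided()` use the two-sided
*method of small p-values*: the p-value sums the probabilities of all
outcomes no more probable than the observed one, with a relative tie
tolerance of 1e-7 to make floating-point ties deterministic. This matches
the standard goodness-of-fit spreadsheets used for tetrad data and agrees
with `fisher.test()`/`binom.test()` (which the test suite uses as an
independent cross-check, alongside from-scratch enumeration). Degenerate
margins return p = 1 with a warning rather than an error, since dissection
tables legitimately produce empty classes.

`genotypeRatioTest()` defaults to the viable class because dead spores
usually cannot be genotyped; when all four genotypes of a tetrad are
needed, missing dead-spore genotypes can be completed by the 2:2 rule
(only when three spores are typed and the completion is forced), and any
use of that inference is flagged in the output.

# Gene-family annotation

* **Motif scanning** is an ungapped sliding identity scan with a default
  threshold of 0.8 — the elements are described as nearly identical across
  genes, and an auditable identity scan is preferable to a probabilistic
  model at that conservation level. Random 400 bp sequences produce no
  hits at this threshold (tested over 100 seeds).
* **Subtype assignment** scans downstream of the intron-1 element for the
  first ATG in frame with the predicted CDS; for intron positions the
  frame is computed as if translation continued through the remaining
  intron into exon 2 (the poison isoform of Intron-1-ATG genes begins with
  a few intron-encoded residues). The search extends a configurable
  150 bp into exon 2; the biological sources describe the search region
  only as the 5' section of exon 2, so the bound is a package decision.
* **Pseudogene calling** compares against a family consensus structure:
  lost start (CDS does not begin with ATG), segmental deletion (missing
  exon, or an exon under 50% of its consensus length), frameshift (spliced
  CDS length differs from consensus mod 3), premature stop (in-frame stop
  before the final 10% of the consensus CDS, evaluated only when the frame
  is intact since stop cascades downstream of an indel are attributed to
  the indel). The 10% and 50% cutoffs are package-defined; the lesion
  categories themselves follow the published classification.
* **Divergent genes** are supplied as an explicit list (the published set
  of eight most-divergent genes has no numeric criterion); precedence is
  lesions → divergent list → motif subtype → antidote-only → unclassified.
* **LTR-deletion detection** requires a directly oriented pair in the
  donor and a solo LTR at the syntenic recipient position, and asks
  whether the solo LTR is an exact prefix-of-copy-A + suffix-of-copy-B
  recombinant. The compatible switch points form an interval whose width
  is the breakpoint homology; the deleted interval is reported at the
  leftmost compatible switch point. Detection is exact on string-surgery
  products by construction.

# Phylogenetic neighbors

* A *neighbor pair* is a cherry — two leaves separated by a single
  internal node — whose support value is at least 95. Support values
  attach to bipartitions, not node indices, so they survive re-rooting;
  cherries lacking support are excluded with a warning.
* `midpointRoot()` places the root halfway along the longest leaf-to-leaf
  path. Ties between equally long paths are broken by the
  lexicographically smallest sorted endpoint pair, making rooting
  deterministic; trees with all-zero branch lengths are rejected
  ("midpoint undefined"). The implementation is validated against a
  closed-form brute-force search over all edges.
* Synteny classification declares a pair syntenic only when both members
  share a syntenic group *and* come from different genomes; same-genome
  pairs (tandem duplicates) are non-syntenic by definition.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to give stable statistics in
seconds on a laptop: 2 000 tetrads for simulator-model agreement (3 SE
criterion), 500 tetrads per cell for parameter recovery, 3 000 SNPs at 15×
over a 2.4 Mb chromosome with 150-colony pools for the scan (10–20 seeded
replicates, median criteria), 200 genes for classification recovery, and
20-leaf trees for rooting oracles. Exact-test oracles enumerate all 2×2
tables with n ≤ 30 and all binomial outcomes with n ≤ 50. Tetrad
enumeration is exact and merges duplicate patterns; it is intended for the
few-locus crosses of this design space and refuses configurations beyond
~2×10⁵ joint states. Probability sums are checked to 1e-12; midpoint
equidistance to 1e-9.

# Known limitations

* The tetrad model has no NPD class and no interference; tetrad-class
  frequencies (PD:NPD:TT) are not faithful even though per-spore marginals
  are — do not use the simulator to study crossover interference.
* Killer fitting assumes the model structure (which killers exist, their
  resistance sets) is known; it estimates penetrance/protection, not the
  number of killers.
* The annotation consensus is structural (exon counts/lengths); it does
  not align sequences, so exon-boundary revisions of the kind occasionally
  needed for real gene models are out of scope.
* Phylogenetic analysis consumes a support-labeled tree; alignment and
  tree inference are external.
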