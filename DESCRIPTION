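Package: wtfDrive
Title: Modeling and Detection of wtf-Family Spore Killers in Fission Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying meiotic drive by poison-antidote spore killers
    of the fission-yeast wtf gene family. Provides an analytic genetic model of
    killer-dependent spore death in tetrads (killing penetrance, antidote
    efficiency, resistance sets) with exact expectations and maximum-likelihood
    parameter fitting; simulators for tetrad dissection data, viable-spore
    pools and pooled-sequencing allele-count tables with known ground truth;
    a bulk-segregant allele-frequency scan with rolling-median smoothing,
    transmission-distortion region detection and donor-segment inference for
    backcrossed strains; exact tetrad statistics (Fisher's exact test and the
    exact binomial goodness-of-fit test by the method of small p-values);
    sequence-feature annotation of wtf-like genes (conserved motif scanning,
    poison-isoform start-codon subtyping, pseudogene lesion calling,
    LTR-mediated deletion detection); and phylogenetic-neighbor analysis on
    support-labeled trees with midpoint rooting and synteny classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    zoo,
    yaml,
    ape,
    phytools,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
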