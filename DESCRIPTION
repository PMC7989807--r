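Package: gapkit
Title: Dual-Strategy Paired-End Amplicon Processing for Functional Genes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes Illumina paired-end amplicon sequencing data for
    functional marker genes of any amplicon size using two complementary
    strategies: scored overlap merging ("assembly") for amplicons shorter
    than twice the read length, and reverse-complement concatenation
    ("gap") for longer amplicons whose paired reads cannot overlap.
    Provides 3' quality trimming, expected-error filtering, dereplication
    with abundance tracking, frame-aware stop-codon filtering, de novo
    two-parent chimera detection, identity-based assignment of sequences
    to reference phylogenetic clusters at multiple thresholds, community
    comparison statistics (Bray-Curtis dissimilarity, Pearson correlation,
    analytic rarefied richness), branch-score tree distance, lineage
    congruence tabulation, canonical correspondence analysis with
    permutation tests, and a fully seeded paired-end read simulator that
    supplies ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
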