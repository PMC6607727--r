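Package: premirscan
Title: Genome-Wide Discovery of Putative Plant Pre-miRNA Hairpins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-free, genome-wide identification of putative plant
    microRNA precursors. Noncoding (intergenic and intronic) space is
    fragmented into fixed-length overlapping windows, screened for
    hairpin-forming fragments, merged into predicted loci, and folded with a
    deterministic maximum-weight base-pairing folder; miRNA duplexes are
    extracted from stem-loops under strand-length, asymmetric-bulge and
    mismatch criteria, with end-extension retry. Predicted loci are validated
    against reference pre-miRNA sets with an exact hypergeometric overlap
    test, supported by small-RNA and total-RNA expression evidence and
    conservation against known plant mature miRNAs, summarised as population
    densities per region class, and linked to candidate target transcripts by
    complementarity scoring with binding-group and degree-class network
    analyses. A seeded synthetic-genome generator with planted hairpins and a
    truth table makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
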