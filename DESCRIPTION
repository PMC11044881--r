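Package: alleleKDE
Title: Kernel Density Estimation of Allele Frequency on Nucleotide Sequence Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates allele frequency mass functions over discrete
    nucleotide sequence space, including the mass carried by alleles that
    were never sampled. A Jukes-Cantor-derived kernel spreads each sampled
    sequence's weight over its mutational neighbourhood; the intractable
    4^l sequence space is compressed to a "distance space" keyed by
    Hamming distances to the detected alleles, optionally truncated by a
    mutation number. Bandwidths are selected by least-squares or
    likelihood cross-validation. Includes an approximate nucleotide
    diversity estimator on the compressed space, a single-deme coalescent
    population simulator with finite-sites Jukes-Cantor mutation, and an
    experiment harness measuring bias, accuracy and concordance of the
    estimates against known populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
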