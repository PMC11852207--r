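Package: shufflonr
Title: Quantitative Analysis of Shufflon Invertase Recombination Assays
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing synthetic shufflon
    reporter assays driven by site-specific shufflon invertases. Provides the
    parity-constrained signed-permutation model of module arrangements,
    rendering of reference amplicon sets, a synthetic library and noisy
    long-read generator, two independent per-read configuration decoders
    (a k-mer marker decoder and an exhaustive edit-distance classifier),
    library statistics (shuffling rate, module occupancy, diversity under
    subsampling, inversion-event depth, module inversion frequency and its
    regression on module length), and a k-mer screen for direct and inverted
    repeats used to reconstruct candidate 31-nt recombination sites from
    flanking DNA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
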