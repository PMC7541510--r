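Package: toeholdr
Title: Sequence-to-Function Modelling and Design of Toehold Switch Riboregulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing and analysing toehold switch riboregulators
    from sequence alone. Provides a configurable structural grammar that
    assembles 59-nt switches from 30-nt trigger RNAs, validates and repairs
    candidate sequences, and tiles genomes into candidate triggers; an
    in-silico corpus generator with a tunable sequence oracle for
    fully-reproducible benchmarking; a two-head convolutional ON/OFF
    regressor and a k-mer recurrent language-model classifier, both trained
    natively with exact input gradients; interpretability tooling (filter
    logos, k-mer enrichment, saliency, in-silico mutagenesis, intrinsic
    attention); and two sequence optimizers: gradient ascent on a relaxed
    nucleotide representation with constraint repair (STORM) and exhaustive
    stem-variant enumeration ranked by a geometric-mean consensus of both
    models (NuSpeak).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
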