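Package: ampliconDel
Title: Quantification of CRISPR-Cas9 Dual-Guide Deletions from Pooled
    Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for measuring the efficiency of CRISPR-Cas9 dual-guide
    (paired cut site) deletions from pooled amplicon sequencing libraries.
    Reads are aligned to the wild-type amplicon with a split aligner that
    allows a single internal deletion junction, junction-spanning
    ("spliced") reads are extracted with configurable junction-size and
    alignment-ratio filters, assigned to sgRNA pairs by cut-site proximity
    windows, and summarised as per-library, per-pair editing efficiencies
    with replicate aggregation and deletion-spectrum output. A seeded
    FASTQ simulator with known ground truth supports validation, and
    companion routines cover the downstream expression statistics of such
    experiments: comparative-CT (delta-delta-Ct) fold changes, percent
    change of staining and immunoblot band intensities, transduction
    efficiency, and Welch t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
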