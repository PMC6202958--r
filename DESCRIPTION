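Package: photomarker
Title: Quantification of Phototrophy Marker Genes in Metagenomes and
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recruits short reads to protein profiles of the phototrophy
    marker genes proteorhodopsin (PR), psaA and pufM and the single-copy
    housekeeping gene recA, assigns proteorhodopsin reads to reference-tree
    leaves and taxonomic clusters, and computes recA-normalized gene
    abundances, RNA:DNA expression ratios, Shannon cluster evenness and
    blue/green spectral-tuning fractions, including the low-chlorophyll
    tuning trend model. Ships a seeded synthetic picoplankton community
    generator with ground-truth tables for benchmarking every estimator,
    and an end-to-end pipeline driver with a YAML configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
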