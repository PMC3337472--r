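Package: mosaicsat
Title: Saturation Statistics and Simulation for F1 Mosaic Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for planning and analysing saturation
    mutagenesis screens carried out by F1 clonal (mosaic) analysis. Provides
    the Poisson screen-design arithmetic (expected lethal-mutation yields,
    per-gene hit rates, genome-coverage probabilities and their inverse),
    saturation and total-locus estimation from an observed allele spectrum by
    both the plug-in Poisson rule and a zero-truncated Poisson maximum
    likelihood correction with bootstrap intervals, complementation-group
    inference from pairwise test matrices with detection of intransitive
    ("complex") complementation and hypomorph candidates, and a stochastic
    simulator of the whole screen (mutagenesis, recovery attrition, penetrance
    filtering, complementation testing) used to validate the estimators by
    parameter recovery. Ships the allele spectrum of a published Drosophila
    miRNA-pathway screen as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
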