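Package: polyfate
Title: Homoeolog Fate and Expression Analysis for Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the fates of duplicated gene copies (homoeologs)
    in allopolyploids with extant diploid progenitors. Identifies
    reciprocal-best-hit ortholog pairs between two parental transcriptome
    assemblies and delimits common orthologous regions (COREs); sorts reads
    aligned against both parental references into parent-diagnostic and
    shared classes; flags COREs with systematic mapping bias from diploid
    data and calls homoeolog-specific expression with a Bayesian posterior
    on the homoeolog proportion under multiple priors; tests mid-parent
    additivity of polyploid expression with precision-weighted linear
    models; classifies each homoeolog as expressed, silenced, lost or
    failed from paired DNA-capture and RNA evidence; and quantifies
    convergence of those states across independently formed polyploid
    lineages. Includes a synthetic-data generator with known truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    limma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
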