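Package: txpredict
Title: Predicting Gene Expression Measures from Transcript Sequence Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a large catalogue of biophysically motivated features from
    the 5'UTR, ORF and 3'UTR of each transcript (lengths and length ratios,
    nucleotide and codon/amino-acid (pair) composition, upstream and shifted
    open reading frames, start-codon context scores, tRNA and codon adaptation
    indices, RNA folding strength, PARS structure profiles, and a ribosome
    traffic (TASEP) translation-rate feature) and predicts five per-gene
    expression measures (mRNA level, protein abundance, ribosomal density,
    proteins per mRNA, ribosomal load) with a jackknifed greedy feature
    selection framework using linear and MARS regressors. Includes a synthetic
    transcriptome and expression generator with planted signal for end-to-end
    validation, an exact small-lattice TASEP solver, and an experiment grid
    runner over targets, transcript segments, inference schemes and model kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
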