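Package: codonpref
Title: Codon Usage Preference Analysis for Extremophile Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of synonymous codon usage between
    extremophilic coding sequences and their non-extremophilic homologs.
    Computes per-CDS codon frequency vectors, filters statistically
    significant codons with the two-sample Kolmogorov-Smirnov test,
    quantifies relative codon abundance and maps codon preference onto a
    1-9 interval scale, summarises AT/GC-richness and wobble-position
    composition, tabulates cross-class codon harmony, and builds
    supervised classifiers with decision-rule extraction over significant
    codon features. Includes a synthetic generator of homologous CDS
    pairs with class-specific synonymous-codon profiles and known
    injected biases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    e1071,
    class,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
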