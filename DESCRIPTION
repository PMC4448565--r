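Package: bcgaelm
Title: Gene Subset Selection by a Binary-Coded Genetic Algorithm Wrapped
    Around an Extreme Learning Machine
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for multi-class expression data.
    Candidate gene subsets are encoded as fixed-length binary chromosomes
    and evolved by a genetic algorithm with normalized geometric ranking
    selection, a hybrid uniform/two-point crossover producing four
    offspring per pair, random mutation, and elitism.  Each subset is
    scored by the mean validation accuracy of an extreme learning machine
    (random hidden layer, analytic Moore-Penrose output weights) over
    repeated stratified 75/25 train/test splits, with a parsimony bonus
    once accuracy exceeds a threshold.  Includes a synthetic multi-class
    expression simulator with planted discriminative genes, readers and
    writers for TSV/CSV and the Broad GCT/RES/CLS dialects, and a
    command-line interface covering simulate, select and classify runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
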