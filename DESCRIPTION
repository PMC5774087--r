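Package: binqtl
Title: Bin-Map Construction and QTL Mapping for Large RIL Populations
    Genotyped at Low Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds recombination-bin maps for large biparental recombinant
    inbred line (RIL) populations from sparse low-coverage
    genotyping-by-sequencing SNP calls, and maps minor-effect quantitative
    trait loci (QTLs) against the resulting bin genotypes. Implements the
    modified sliding-window genotype caller with breakpoint-midpoint
    resolution and block/line filters, population-wide bin construction with
    segregation-distortion screening, Viterbi genotype imputation, genetic
    map estimation through the Kosambi map function with the selfed-RIL
    recombination correction, recombination-landscape profiling, a composite
    interval mapping style genome scan with stepwise cofactor selection,
    permutation-based significance thresholds, 1.5-LOD support intervals,
    additive effects and variance explained, multi-environment BLUPs and
    heritability, and recombinant-derived progeny-test interval refinement.
    A meiosis-level population simulator (selfing by single-seed descent,
    Poisson crossovers) generates GBS-like data so the whole pipeline is
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
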