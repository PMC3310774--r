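Package: bindingQTL
Title: Genotype Effects on Transcription Factor Occupancy in a Pedigree
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of quantitative effects of DNA sequence
    variation on transcription factor occupancy measured by ChIP-seq across a
    three-generation pedigree. Provides a synthetic study generator (Mendelian
    transmission with recombination and truth identity-by-descent, position
    weight matrix scored binding sites, negative-binomially dispersed ChIP-seq
    counts under a saturating occupancy model, allele-partitioned read counts,
    resequencing pileups), PWM scanning with exact score p-values and allele
    log-odds deltas, tag-density signal processing with a read-simulation
    mappability filter, SNP calling with Mendelian-consistency screening,
    negative binomial regression of occupancy on genotype with additive and
    dominant model selection and Storey or Benjamini-Hochberg FDR control,
    allele-specific occupancy tests, aggregate Haseman-Elston sib-pair linkage
    with structure-preserving permutation, buffering analyses (substitution
    grids, occupancy deciles, mutual-information context dependence,
    occupancy clustering), and predictor evaluation by ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
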