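Package: barrierscan
Title: Combinatorial Scans for Barrier Loci and Sexually Selected Variation in
    Contact Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether loci underlying intraspecific mating
    traits coincide with interspecific barrier loci in a two-species contact
    zone. Implements site-wise Weir-Cockerham FST, windowed nucleotide
    diversity and dXY with callable-site denominators, Patterson's D and f4
    with block-jackknife significance across population trios, joint
    site-frequency-spectrum demographic model comparison with a Monte Carlo
    structured coalescent, EHH/iHS selective-sweep scans, kinship-corrected
    linear-mixed-model trait association, latent-factor genotype-environment
    association with genomic-inflation calibration, LD pruning, genotype PCA
    and simplex-constrained ancestry estimation, plus quantile-outlier
    integration over gene annotations. Ships a synthetic contact-zone data
    generator with planted truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
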