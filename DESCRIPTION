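Package: popgenscan
Title: Population Structure and Natural-Selection Scans for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting fine-scale population structure and
    signatures of recent positive selection from diploid SNP genotype
    panels. Implements genotype and haplotype containers with sample and
    marker metadata, quality control (call-rate filters, exact
    Hardy-Weinberg testing with Bonferroni correction, moments-based
    relatedness pruning, LD pruning), principal component analysis with
    Patterson scaling, Procrustes projection of genetic structure onto
    geography with a permutation test, discriminant analysis of principal
    components, the f3 admixture statistic with block-jackknife Z-scores,
    and a three-pronged selection scan: MAF-binned Weir-Cockerham Fst
    outliers, bin-standardized integrated haplotype scores (iHS) from
    extended haplotype homozygosity, a joint 200-kb window ranking, and
    derived-allele-frequency differentiation tests with a
    drift-background correction. A Balding-Nichols simulator generates
    structured, phased datasets with planted differentiated loci, planted
    sweeps and QC defects as ground truth for the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    vegan,
    vcfR,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
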