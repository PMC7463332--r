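Package: palmdiv
Title: Clonal Identity and Agrobiodiversity Analysis of Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codominant microsatellite (SSR) genotypes of
    clonally propagated crops, built around an oasis date-palm study design:
    multilocus genotype identity and clone-line detection with somatic-mutation
    tolerance, classification of locally named types into true-to-type cultivars,
    ethnovarieties and local categories, per-locus diversity statistics (PIC, null
    alleles, Hardy-Weinberg tests), rarefied allelic and private allelic richness,
    Weir-Cockerham FST, Nei distances with bootstrapped neighbor-joining trees,
    allele-dosage PCA, a Gibbs-sampling admixture model with Evanno delta-K model
    selection, plastid chlorotype assignment, and a synthetic cohort generator that
    emulates the study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
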