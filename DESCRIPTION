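Package: sirpheno
Title: Multiple-Phenotype Genetic Association Tests via Sliced Inverse Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Association testing between multiple continuous phenotypes and
    multi-SNP genotypes via sufficient dimension reduction. Phenotypes are
    reduced to a single index by sliced inverse regression (SIR) of the
    standardized traits on genotype slices (exhaustive genotype-pattern
    slices, or slices formed from a genetic relatedness matrix for larger
    SNP panels), and association is assessed by permutation-calibrated
    Wald tests: a global test over all SNPs and a per-SNP test with
    Bonferroni adjustment. Includes classical multivariate Wald baselines,
    principal-component combination tests, and a simulation harness for
    type-I-error and power studies under Hardy-Weinberg genotypes and
    AR(1)-correlated normal traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, optparse, vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
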