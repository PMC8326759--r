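Package: multiblup
Title: Multi-Component Genomic Prediction for Low-Heritability Survival
    Traits with De-Regressed Proofs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree and multi-component genomic best linear unbiased
    prediction (PBLUP/GBLUP) for dairy-cattle young-stock-survival traits
    using de-regressed proofs (DRP) with heterogeneous residual weights.
    Provides VanRaden method-1 genomic relationship matrices per SNP set,
    the tabular pedigree relationship matrix with a generation-limited
    ancestor trace, average-information REML with EM fallback for one- to
    three-component models including random regression on recessive-lethal
    marker genotypes, forward validation by birth year with predictive
    reliability and dispersion bias, genomic variance-share decomposition,
    and a gene-drop simulator of Holstein-like populations for testing the
    whole pipeline without restricted industry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
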