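Package: triadmix
Title: PCA-Free Continental Ancestry Inference from Fingerprint SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places genotyped subjects in a fixed coordinate system defined by
    expected Hardy-Weinberg genotype log-likelihood distances to five reference
    populations, estimates continental ancestry proportions via barycentric
    coordinates on a reference triangle built from three anchor groups, and
    assigns one of nine population labels from explicit cutoff rules. The
    normalization onto subject-specific subset triangles makes placements
    robust to high and platform-structured genotype missingness, so cohorts
    genotyped on different platforms remain directly comparable. Includes
    readers for PLINK 1 bed/bim/fam and VCF with allele harmonization, a
    synthetic reference-panel and cohort simulator, diagnostic plots, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
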