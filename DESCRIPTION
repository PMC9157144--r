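Package: paleoimpute
Title: Evaluation of Genotype Imputation for Low-Coverage Ancient DNA
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained framework for studying genotype imputation of
    ancient DNA from genotype likelihoods. Simulates phased reference panels
    and damaged low-coverage ancient-like read data (sequencing error and
    post-mortem C-to-T / G-to-A deamination), computes biallelic genotype
    likelihoods with high-quality gold-standard calling and deamination-aware
    site filtering, imputes posterior genotype probabilities with a diploid
    Li-Stephens haplotype-copying hidden Markov model (single-sample and joint
    study-sample modes, windowed over long marker sets), and evaluates results
    with overlap-stratified genotype concordance, minor-allele-frequency-binned
    heterozygote discordance, reference-affinity difference curves, posterior
    probability filtering, and principal component projection of samples with
    missing data via known data regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
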