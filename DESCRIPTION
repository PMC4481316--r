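Package: shotgunfm
Title: Stochastic Shotgun Search for Multi-SNP Fine Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian variable selection for fine mapping densely genotyped
    association regions that may contain multiple causal variants. Variants in
    extreme linkage disequilibrium are clustered into tagsets; multi-SNP
    regression models over the tag SNPs are explored by a seeded stochastic
    shotgun search scored with BIC-approximate Bayes factors under a binomial
    model-size prior; the best tag models are expanded by substituting tagset
    members and rescored; and the posterior is summarised as disjoint SNP
    groups (a multi-causal analogue of credible sets) with marginal and group
    posterior probabilities of inclusion. Includes a forward stepwise
    regression baseline with r-squared pseudo credible sets, an LD-structured
    genotype and phenotype simulator, and discovery-rate and
    false-discovery-rate benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
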