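Package: condlogdet
Title: Conditioned Logdet Phylogenies from Gene Content with Heterotachy
    Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates phylogenies from binary gene-family presence/absence
    matrices by conditioned genome reconstruction: logdet (paralinear)
    distances computed on the families present in each conditioning genome
    in turn, delta-method variances, repair of non-existent distances by
    pseudocounts or constrained maximum likelihood, inverse-variance
    combination across conditioning genomes, and a variance-weighted BIONJ
    supertree. Includes two mixture models for heterotachous gene loss in
    intracellular parasites (a non-phylogenetic binomial mixture fitted by
    EM and a phylogenetic two-category gain-loss mixture with discrete
    gamma rate classes), empirical-Bayes family classification,
    per-category distance pipelines, a gene-content simulator, and
    comparison statistics (SHOT distances, Robinson-Foulds distances,
    majority-rule consensus, chi-squared assignment association).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
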