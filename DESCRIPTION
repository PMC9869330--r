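Package: hdpsig
Title: Mutational Signature Discovery with Hierarchical Dirichlet Process
    Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers mutational signatures from catalogs of tumor mutation
    spectra (SBS-96 or ID-83 classifications) using hierarchical Dirichlet
    process mixture models sampled by a Chinese-restaurant-franchise Gibbs
    sampler. Posterior mutation clusters are grouped by divisive hierarchical
    clustering on cosine distance and retained by their posterior support.
    Includes proportional downsampling of hypermutated spectra, a
    negative-binomial generator of realistic synthetic catalogs with known
    ground truth, Hungarian-algorithm matching of discovered signatures to
    ground truth with PPV/TPR/cosine metrics, and non-negative least-squares
    reconstruction of signatures from a reference set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    parallel,
    fitdistrplus,
    pracma,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
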