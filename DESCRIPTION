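Package: admixdemo
Title: Demographic Inference for Admixed Populations from Ancestry Tracts,
    IBD Sharing, and Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the demographic history of three-way admixed
    American populations. Implements the analytic length distribution of local
    ancestry tracts under time-varying migration with Poisson maximum-likelihood
    fitting and model selection; effective population size estimation from
    identity-by-descent (IBD) segment counts together with IBD/ancestry
    consistency statistics; negative ascertainment of variants private to the
    Native American background with an empirical singleton-bias correction; a
    deterministic frequency-grid engine for expected joint site frequency
    spectra under three-population split models fit by pairwise composite
    likelihood; and an expectation-maximization estimator of ancestry-specific
    allele frequencies from unphased genotypes with diploid local-ancestry
    calls. A full synthetic-data generator (forward Wright-Fisher chromosome
    painting, genotypes on ancestry backgrounds, split-model allele frequency
    simulation, IBD sharing) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
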