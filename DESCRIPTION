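Package: stairbayes
Title: Bayesian Stairway-Plot Inference of Demographic History from
    Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference of single-population demographic histories
    from site frequency spectra using the stairway-plot composite
    (multinomial) likelihood built from expected coalescent times. One
    scaled population size (theta = 4*N*mu) is estimated per coalescent
    interval under a choice of nine prior models: independent uniform,
    lognormal and gamma priors, the grouped Bayesian skyline plot,
    reversible-jump grouping, and first- and second-order Gaussian and
    Horseshoe Markov random fields. Includes Metropolis-within-Gibbs MCMC
    with replicate runs and convergence summaries, leave-one-out
    cross-validation (LPCV) model selection computed posthoc from stored
    site-class probabilities, transformation of theta samples to population
    size trajectories with credible bands, folded-spectrum and
    ascertainment-corrected likelihoods, and a synthetic-data generator for
    standard demographic scenarios including ancestral-allele
    polarization error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
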