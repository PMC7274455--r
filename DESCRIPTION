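Package: tsbm
Title: Temporal Stochastic Block Models for Developing Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the community structure of in vitro
    neuronal cultures on multi-electrode arrays evolves over days in vitro.
    Builds binary functional networks from spike-timestamp recordings via
    channel-burst and global-burst detection, burst-windowed cross-correlation
    and thresholding; simulates and fits a temporal stochastic block model in
    which community-pair edge probabilities follow latent Gaussian processes
    through a logistic link; provides MCMC inference with categorical Gibbs
    updates for community labels and elliptical slice sampling for the latent
    functions, size-ordered relabeling, adjusted mutual information recovery
    scores, Gaussian-process interpolation and prediction of connection
    probabilities at unobserved days, held-out predictive likelihood, and
    condition-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
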