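Package: erfield
Title: Electrical Receptive Fields of Retinal Neurons from Multi-Electrode
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and validation of spatiotemporal electrical receptive
    fields (ERFs) of retinal ganglion cells stimulated with multi-electrode
    white-noise pulse trains. Implements a Generalized Quadratic Model (GQM)
    with excitatory and suppressive filter components fitted by Poisson
    maximum likelihood, initialized from spike-triggered average and
    covariance (STA/STC) analysis with a shuffle-based eigenvalue
    significance test. Includes bootstrap significance testing of electrode
    contributions, cross-validated prediction diagnostics with a simulated
    Poisson best-case ceiling, one- and two-dimensional spike-triggered
    covariance baseline models, structured (spot, line and grating) stimulus
    generation, and a synthetic ground-truth cell simulator for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
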