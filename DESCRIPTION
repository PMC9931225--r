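Package: sepsisrl
Title: Physiology-Constrained Distributional Reinforcement Learning for
    Sepsis Treatment Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns uncertainty-aware fluid and vasopressor treatment
    policies for septic ICU patients from hourly trajectories. Latent
    cardiovascular state (systemic vascular resistance, arterial
    capacitance, stroke volume, filling time) is inferred with a denoising
    recurrent autoencoder whose fixed decoder is the two-element Windkessel
    pressure model; laboratory history is compressed with a stacked
    denoising recurrent autoencoder; a categorical distributional Q-learning
    agent (51 fixed return atoms) is trained offline on the assembled
    41-dimensional state space with outcome-weighted experience sampling;
    epistemic uncertainty is estimated as the mean Kullback-Leibler
    divergence of a bootstrap ensemble from its reference distribution; and
    recommendations arbitrate between agent, clinician behavior cloner and
    uncertainty through an action preference score. Includes a seeded
    synthetic ICU cohort simulator with ground-truth hemodynamics for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
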