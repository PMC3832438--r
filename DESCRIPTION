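Package: thrombolyzer
Title: Thrombolysis Scoring and Simulation for Arterial Occlusion Flow Studies
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Quantitative assessment of thrombolytic efficacy in the ferric
    chloride carotid thrombosis model: blood-flow trace scoring
    (thrombolysis score as percent of baseline flow), sustained-threshold
    detection of complete occlusion, effective recanalization and
    reocclusion, impedance platelet aggregometry inhibition and
    disaggregation statistics, dissociation-constant estimation from ELISA
    titrations by the 1/(1-i) versus [L]/i linearization, and log-linear
    half-life fitting. Includes a pharmacokinetics-driven thrombosis/lysis
    simulator (one-compartment bolus plus infusion model coupled to a
    latent thrombus-burden state) that generates every supported input type
    for reproducible desk-scale studies, plus study orchestration and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
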