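Package: hemiconn
Title: Hemispheric Connectome-Based Prediction of Motor Improvement
    After Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Connectome-based predictive modelling of the motor improvement
    rate (delta UPDRS-III) after subthalamic deep brain stimulation from
    pre-surgical resting-state functional connectivity. The whole-brain
    Pearson connectivity matrix on a 246-region bilateral parcellation is
    partitioned into left intra-hemispheric, right intra-hemispheric,
    inter-hemispheric homotopic, and inter-hemispheric heterotopic edge sets;
    within each network, edges are screened by random-forest out-of-bag
    permutation importance and the outcome is predicted by ridge regression
    under nested cross-validation (outer leave-one-out, inner five-fold grid
    search). Includes a synthetic cohort generator with planted edge-outcome
    effects for validation, group (age/sex) analyses, and gyrus-level
    reporting of the top predictive connections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    ranger,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
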