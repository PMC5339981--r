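Package: stenoflow
Title: Multi-Directional Phase-Contrast CMR Flow Quantification for Aortic Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies aortic-stenosis hemodynamics from phase-contrast
    cardiovascular magnetic resonance velocity maps. Provides a synthetic
    dynamic flow-phantom generator with a simulated Doppler
    echocardiography arm, balanced four-point velocity encoding and
    scanner-style decoding with velocity-aliasing detection and
    phase-unwrapping salvage, magnitude and flow thresholding, speed maps,
    peak-velocity curves, Bernoulli pressure gradients, velocity-time
    integrals, through-plane stroke volume, continuity-equation aortic
    valve areas, and the method-comparison statistics (Pearson correlation
    with Fisher-z intervals, Bland-Altman agreement, comparison of
    dependent correlations) needed to contrast single-direction and
    three-direction analyses against echocardiography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    pracma,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
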