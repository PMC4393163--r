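Package: swaylab
Title: Universal and Individual-Specific Sway Index Classification for Posturography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes 73 classical sway indices from center-of-pressure (CoP)
    recordings of quiet standing (positional, spectral, sway-density,
    stabilogram-diffusion and velocity-interval measures) and classifies them
    into universal, individual-specific and other groups.  The classification
    pipeline standardizes indices as pooled z-scores, screens them per subject
    with Lilliefors' normality test, selects individual-specific candidates by
    AIC-stepwise multi-class linear discriminant analysis with apparent and
    leave-one-out error rates, selects universal candidates on the VM-VV plane,
    expands both groups by pairwise correlation, and validates universal
    candidates by REML variance decomposition over subject, day and time-of-day
    factors.  A hierarchical synthetic CoP generator with slow power-law,
    fast (0.5-1.0 Hz) and very fast (1.0-2.5 Hz) oscillatory components and
    body-parameter-coupled dynamics provides ground-truth-bearing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    nortest,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
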