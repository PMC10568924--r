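Package: usvtools
Title: Adaptive-Threshold Detection and Mixed-Model Analysis of Rat
    Ultrasonic Vocalisations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rat 50-kHz and 22-kHz ultrasonic vocalisations (USVs) in
    ultrasonic audio with a per-frame adaptive spectrogram threshold (mean plus
    a multiple of the cross-band standard deviation), a two-pass sliding-window
    scheme with interval merging, and a duration filter. Builds the session-level
    behavioural variables used in human-rat play ("tickling") studies: per-session
    call counts, per-contact-period emission rates and the play asymmetry score.
    Fits the downstream statistical stage (Poisson GLM on pinnings, Gaussian and
    Poisson mixed models on call counts, AICc model ranking, variance-component
    repeatability with parametric-bootstrap intervals, estimated marginal means)
    and ships seeded generators for synthetic ultrasonic recordings with ground
    truth and cohort-structured behavioural tables so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
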