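Package: deadregion
Title: Bayesian Active-Learning Estimation of Cochlear Dead-Region Edge Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the edge frequency of a basal cochlear dead region
    from yes/no tone-in-noise judgments. A rounded-exponential (roex)
    excitation-pattern hearing model predicts the detectability of a fixed
    probe tone under a narrowband masker; a discrete-grid Bayesian engine
    infers the edge frequency and the outer-hair-cell loss at that place;
    each trial's masker frequency and level are chosen by a greedy
    mutual-information (active-learning) rule. Also provides the quick
    threshold-equalizing-noise screening cascade that fixes the probe,
    a simulated-listener cohort so the whole procedure can be validated
    without human subjects, and post-hoc consistency diagnostics
    (false-alarm rate, psychometric-slope estimation with outlier
    rejection, and convergence measures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
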