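Package: sunkddm
Title: Change-of-Mind Drift-Diffusion Simulation and Sunk-Cost Analysis for
    Foraging Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a change-of-mind drift-diffusion agent performing a
    delay-based foraging task with separate accept (offer-zone) and quit
    (wait-zone) decisions, including expanding, flat, collapsing and
    decision-time-gated quit-threshold variants. Provides the full analysis
    pipeline for sunk-cost sensitivity in such tasks: p(Earn) matrices over
    (time-spent, time-remaining) states, the sunk-cost bubble, baseline slope,
    attrition bias, grid maximum-likelihood thresholds, probit psychometric
    fits with a hyperbolic tangent-to-sigma_W calibration, latency to
    sunk-cost accrual, value-conditioned rank tests, and linear-versus-
    quadratic convexity comparisons. Includes parameter-sweep, calibration,
    reset-hypothesis and mesh-comparison experiment drivers, plus an
    independent hazard-model session generator with a closed-form earning
    oracle for validating the measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
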