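Package: hiitsim
Title: Feasibility Simulation of High-Intensity Interval Training Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether exhaustion-targeted high-intensity interval
    training (HIIT) prescriptions in cycling are physically achievable. Given an
    athlete's power-duration profile, the package solves the work-interval
    intensity that drives two widely used prescription models to exhaustion --
    the Skiba W'-balance model (anaerobic reserve depletion above critical power
    and exponential reconstitution below it) and a Coggan-Modified model that
    equates the session's Normalized Power with the athlete's maximal power over
    the session duration -- then classifies a prescription as impossible when
    the solved intensity strictly exceeds the athlete's best power over the
    work-interval duration. Includes power-duration profile handling with
    log-linear interpolation, critical-power estimation by the linear
    work-duration fit, a deterministic session-grid simulator with grouped
    feasibility summaries, a parametric synthetic-profile generator, and tidy
    outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
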