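Package: oida
Title: Optimal Stimulation-Interval Detection for FES-Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines per-muscle electrical-stimulation intervals for
    functional electrical stimulation (FES) cycling from logged crank-angle,
    crank-torque and thigh-angle streams. Accepted pedalling cycles are
    resampled onto a fixed position template, passive (unstimulated) and
    active (stimulated) torque profiles are averaged, and the optimal
    stimulation interval is located as the positive run of the net torque
    (active minus passive) around its maximum. Cadence-dependent compensation
    of sensor and muscle latencies converts detected intervals into real-time
    stimulation commands, and a pedalling simulator with known ground-truth
    muscle contributions makes the whole pipeline testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
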