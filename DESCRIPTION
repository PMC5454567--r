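Package: legdose
Title: Exercise Dose Quantification and Adherence Monitoring for an
    Instrumented Leg Trainer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for web-enabled exercise telemetry from a resistance
    leg-training device instrumented with a temperature sensor. The rise of
    temperature in the resistance unit (delta-t) is used as a proxy for leg
    work output. The package simulates minute-resolution telemetry for five
    training protocols (moderate-intensity continuous training, dosed MICT at
    100 +/- 10 BPM for 30 minutes, a modified Wingate interval protocol, and
    opportunistic desk or in-bed exercise), segments active training bouts
    from delta-t traces, classifies the training regimen, inverts the thermal
    model to estimate work output, personalizes daily exercise doses as the
    delta-t reached by 30 minutes of dosed MICT, detects dose-completion
    events with daily debouncing, and reports weekly adherence (5 or more
    dose days = compliant) for individuals and cohorts, with a command-line
    pipeline for reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
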