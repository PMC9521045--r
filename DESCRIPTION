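Package: lactecon
Title: Herd Lactation Curve Characteristics and Income over Feed Cost
Version: 0.1.0
Authors@R: person("Analytics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the shape of the herd-level lactation curve
    against average 305-day milk production as explanations of variation in
    dairy herd income over feed cost (IOFC). Provides MilkBot lactation curve
    evaluation and nonlinear least-squares fitting with persistency
    derivation, test-day-weighted partitioning of lactations across calendar
    years with weighted-median aggregation to herd lactation curve
    characteristics (HLCC), construction of economic indicators (IOFC per cow
    and per 100 kg milk, equity ratio, expansion rate, herd intensity,
    relative milk price), a data-editing cascade with an audit log, linear
    mixed models with forced year effects, AIC backward selection and
    marginal/conditional/part R-squared decomposition, Cox and J tests for
    non-nested model comparison, and a synthetic herd data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
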