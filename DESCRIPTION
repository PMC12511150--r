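Package: reachkin
Title: Kinematic Analysis of Upper-Limb Pointing Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing motion-capture recordings of
    point-to-point reaching movements. Trajectories are low-pass filtered with
    a zero-phase Butterworth filter, differentiated to tangential speed and
    scalar acceleration, segmented by a 10 percent-of-peak-speed threshold,
    and summarised by seven kinematic landmarks (movement duration, peak
    velocity, peak acceleration, peak deceleration, and the relative times to
    the three extrema). Condition-level inference follows a normality-gated
    branch: three-way repeated-measures ANOVA with Greenhouse-Geisser
    correction, or Friedman plus Wilcoxon signed-rank tests, with a fixed set
    of sixteen Bonferroni-corrected planned comparisons. Time-resolved
    group differences are tested with one-dimensional statistical parametric
    mapping (paired SPM{t}) using random-field-theory thresholds and
    suprathreshold-cluster reporting. A synthetic-trajectory generator
    emulates a factorial pointing experiment with gravity-like
    velocity-profile asymmetries so every stage is testable without raw
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite
Config/testthat/edition: 3
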