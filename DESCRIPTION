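Package: gazecone
Title: Simulation and Analysis of Gaze-Cone Measurement Methods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring the cone of direct gaze with three classic
    psychophysical tasks: a dyadic yes/no task analysed by the method of
    constant stimuli, a method-of-adjustment task with ascending and
    descending series, and a triadic gaze-direction estimation task.
    Includes a generative observer model for simulating trial-level data
    from all three tasks, maximum-likelihood psychometric fitting
    (cumulative Gaussian and Gaussian bell), piece-wise linear regression
    of triadic reports with a segment-based threshold correction, and
    cohort-level comparison statistics (paired t, Pearson correlation,
    repeated-measures ANOVA).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
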