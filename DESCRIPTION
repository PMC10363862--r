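Package: rotaspeech
Title: Binaural Speech Intelligibility During Self-Rotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models speech intelligibility in a reverberant room while the
    listener rotates. Couples a shoebox image-source room simulation and a
    spherical-head binaural receiver with a better-ear plus binaural-unmasking
    speech intelligibility model to produce head-orientation benefit maps, and
    converts head-yaw trajectories into per-word predicted benefit. Provides
    the accompanying behavioural statistics: circular summaries and a
    permutation two-sample Kuiper test, rationalized arcsine (RAU) scoring,
    random-intercept logistic psychometric fitting, and fully-within-subject
    repeated-measures ANOVA with Greenhouse-Geisser correction. A synthetic
    cohort generator emulates the block/trial design, rotation trajectories
    and psychometrically driven word responses of a self-rotation speech test,
    so the full analysis pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
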