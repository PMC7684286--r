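Package: pitchsubs
Title: Pitch-Reinforcement Analysis and Intrinsically Motivated Agents for
    Sensory-Substitution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop operant pitch-conditioning experiments in
    songbirds in which auditory feedback is substituted by a binary visual
    stimulus (brief light-off contingent on syllable pitch crossing a
    threshold). Implements the behavioral statistics of such paradigms
    (per-day pitch summaries, d-prime daily change series, adaptive median
    threshold controller, start/end criteria, direction and magnitude
    measures, within-syllable pitch-trace d-prime, binomial direction tests),
    linear mixed-effect models for daily pitch change and singing rate with
    matched-control random-pairing robustness tests, acoustic feature
    computations (Harmonic Product Spectrum pitch, log-power spectrograms,
    Wiener entropy, spectrogram bias-variance decomposition), a synthetic
    cohort generator that emulates the statistical structure of the recorded
    data for all treatment groups, and a tabular SARSA agent on a discrete
    syllable-production world whose intrinsic reward combines an
    information-gain exploration bonus with a Kullback-Leibler manipulation
    (impact) bonus, together with cohort-level simulation protocols
    (reinforcement sweeps, ablations, random-reinforcement runs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
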