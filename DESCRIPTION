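Package: flymaze
Title: Choice-Maze Visual Psychophysics for Drosophila: Stimuli, Spectra,
    Maze Simulation and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the automated Drosophila choice-maze visual
    psychophysics paradigm. Renders parameterized moving stimuli (square-wave
    gratings, random-dot kinematograms, superimposed competition movies and
    1/f synthetic textures) as deterministic, seedable frame sequences;
    quantifies image regularity as the peak of the frame-averaged horizontal
    spatial-frequency power spectrum; simulates populations of flies
    traversing an 8-junction binary-choice maze with nine ranked exit tubes
    under a stimulus-dependent turning bias; computes the Visual Response
    (VR) population statistic with direction balancing; and provides the
    accompanying statistical pipeline (Monte-Carlo Lilliefors normality
    screening, tests against zero and between strains, one-way ANOVA with
    Tukey compact letter displays, pairwise correlation tables, and
    VR-versus-peak-power meta-analysis fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    nortest,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
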