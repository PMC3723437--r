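Package: bciwalk
Title: Self-Paced Brain-Computer Interface Walking Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Offline and simulated-online analysis for a self-paced
    electroencephalography (EEG) brain-computer interface that decodes idling
    versus walking kinesthetic motor imagery. Provides a seeded synthetic EEG
    session generator with event-related desynchronization of a narrow-band
    sensorimotor rhythm, spectral preprocessing into 2-Hz binned power trials,
    classwise principal component analysis with linear discriminant or
    approximate information discriminant feature extraction and a linear
    Bayesian classifier, cross-validated frequency-band search, a hysteresis
    state machine driving an avatar along a 10-stop virtual course,
    random-walk Monte Carlo null ensembles, Parzen-window two-dimensional
    p-values certifying purposeful control, and a composite performance score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    MASS
Config/testthat/edition: 3
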