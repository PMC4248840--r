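Package: workloadbci
Title: Passive BCI Workload Classification with Test-Time Noise Injection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for passive brain-computer
    interface (BCI) operator-workload monitoring from multi-channel EEG.
    Provides a synthetic EEG study generator with controllable spectral
    workload signatures (alpha/theta modulation over a 1/f background) and
    session-to-session drift, FFT band-power feature extraction, a
    feedforward neural-network workload classifier trained by scaled
    conjugate gradients with early stopping and random restarts, a
    test-time white-noise injection ensemble with majority voting
    (a stochastic-resonance probe), same-session and cross-session
    temporal evaluation protocols, chance-level resampling, and exact
    binomial statistics for paired run comparisons. Includes EDF and
    plain-text I/O for recordings, labels and study manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
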