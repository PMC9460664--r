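Package: eegscrub
Title: Single-Channel EEG Artifact Removal via Variational Mode
    Decomposition and Second-Order Blind Identification
Version: 0.1.0
Authors@R:
    person("eegscrub", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes ocular (EOG) and muscular (EMG) artifacts from a
    single-channel electroencephalogram. The signal is decomposed into
    narrow-band intrinsic mode functions by variational mode decomposition
    (VMD), the mode matrix is separated into statistically independent
    components by second-order blind identification (SOBI, whitening plus
    joint approximate diagonalization of time-lagged covariances), artifact
    components are identified by their fuzzy entropy, and the clean EEG is
    reconstructed from the retained components. Includes an automatic
    selection rule for the number of VMD modes based on invalid center
    frequencies, a seeded band-limited semi-simulation generator for
    testing, signal-quality metrics (SNR, RRMSE, correlation), and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
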