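Package: synconduct
Title: Synaptic Conductance Analysis and Simulation for Retinal Ganglion Cell Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis chain for patch-clamp and loose-patch recordings from
    retinal neurons: spike detection by a derivative threshold, spike blanking,
    peristimulus time histograms and background/peak/sustained rate metrics;
    baseline noise statistics and Campbell-theorem shot-noise moments;
    decomposition of voltage-clamp current-voltage families into excitatory,
    inhibitory and NMDA-type synaptic conductances with an explicit magnesium
    block nonlinearity; linear I-V fits for agonist-evoked currents; and
    drug-condition difference analyses.  Includes a conductance-based
    integrate-and-fire ganglion-cell simulator driven by stimulus-modulated
    Poisson shot-noise excitation, so every analysis stage is verifiable by
    parameter recovery on synthetic recordings, plus a small module for
    cluster-level single-cell expression summaries (mean log(TPM+1), percent
    expressing, ratio-of-means fold differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
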