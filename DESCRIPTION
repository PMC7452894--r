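Package: scrunchFRET
Title: Simulation and Kinetic Analysis of Single-Molecule FRET Traces of
    Transcription Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing two-colour single-molecule
    FRET recordings of DNA bending and scrunching during transcription
    initiation. Provides exact Gillespie simulation of conformational
    kinetic schemes with time-varying nucleotide availability, a forward
    photophysics model (detection-efficiency asymmetry, donor leakage,
    acceptor direct excitation, shot noise, photobleaching), intensity
    corrections and FRET efficiency calculation, Gaussian mixture
    decomposition of FRET histograms, pooled maximum-likelihood hidden
    Markov modelling with Viterbi decoding and transition density plots,
    dwell-time, washout and exponential-decay kinetics, branching
    classification of post-washout trajectories, and conversion of FRET
    efficiencies to donor-acceptor distances under a fixed-bend scrunching
    geometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
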