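Package: cisync
Title: Neural Synchrony Modeling for Cochlear Implant Stimulation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation pipeline for comparing phase locking of the auditory
    nerve under acoustic and electric (cochlear implant) stimulation. Generates
    pure and harmonic complex tones, processes them through a 22-channel
    logarithmic filterbank and emulations of the CIS, HDCIS, PDT and HD-ACE
    pulse-coding strategies, propagates the resulting biphasic pulse trains
    through an inverse-law current-spread model of a linear electrode array,
    and drives a stochastic point-process model of auditory-nerve fibers.
    Synchrony is quantified by spike and charge-weighted vector strength,
    interspike-interval histograms and excitation profiles, with experiment
    drivers for frequency sweeps and stimulation-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
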