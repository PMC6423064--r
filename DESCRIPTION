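Package: eegevents
Title: Three-Pass Hybrid Classification of Clinical EEG Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for six-way classification of clinical EEG events (spike
    and sharp waves, periodic lateralized and generalized periodic
    epileptiform discharges, eye movement, artifact and background) from
    multichannel recordings. Implements a three-pass architecture: linear
    frequency cepstral coefficient features with energy and differential
    energy terms; per-channel sequential decoding with left-to-right
    Gaussian-mixture hidden Markov models trained by Baum-Welch; stacked
    denoising autoencoder post-processing that integrates spatial and
    temporal context; and an iterative Bayesian smoother driven by a bigram
    class-transition grammar. Includes EDF signal input/output with bipolar
    TCP montage support, a synthetic annotated-corpus generator for testing,
    and event-based and epoch-based scoring with DET curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
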