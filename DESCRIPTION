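Package: AmpEntropy
Title: Amplitude Entropy for Multichannel Neural Recordings
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Time- and frequency-resolved quantification of cross-channel
    amplitude heterogeneity in multichannel electrophysiological recordings.
    Signals are band-pass filtered into clinical frequency bands with a
    zero-phase fourth-order Butterworth cascade, converted to instantaneous
    analytic amplitudes (Hilbert envelopes), and summarized at every time
    point by the Shannon entropy of the fixed-width-binned amplitude
    distribution across channels (Amplitude Entropy, AE). Includes
    variable-length seizure segment alignment with NaN padding, two-step
    (seizure then patient) grand averaging, linear mixed-effects testing of
    segment differences, nonparametric post-hoc association tests, and
    synthetic ground-truth generators (a Stuart-Landau ring network with
    amplitude-chimera regimes and a pink-noise seizure surrogate cohort).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'bands.R'
    'recording-io.R'
    'filtering.R'
    'hilbert.R'
    'entropy.R'
    'aggregate.R'
    'stats.R'
    'synth.R'
    'pipeline.R'
    'cli.R'
    'AmpEntropy-package.R'
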