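Package: stimdither
Title: Dynamically Optimized Electrical Stimulation by Greedy Temporal Dithering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and optimizer for encoding visual stimuli into
    temporally dithered, spatially multiplexed sequences of single-electrode
    electrical stimuli for epiretinal implants. Implements linear
    reconstruction of retinal ganglion cell (RGC) population responses, a
    bias-variance expected-error objective for Bernoulli spike responses,
    greedy per-step stimulus selection with refractory masking and
    exclusion-radius multiplexing, convex lower bounds (relaxed joint
    optimization and perfect control), a static pixel-wise baseline
    approximating existing implants, sigmoid activation-curve calibration
    analysis, electrode-usage and dictionary-subsampling analysis, a
    natural-scene extension with saccadic and fixational eye movements and a
    rank-1 spatiotemporal reconstruction filter, and joint patch optimization
    under MSE or SSIM objectives with an L1 stimulation budget. Includes a
    synthetic retina fixture generator (electrode lattices, ON/OFF mosaics of
    signed Gaussian filters, distance-dependent sigmoidal activation
    dictionaries, checkerboard targets) so all analyses run without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
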