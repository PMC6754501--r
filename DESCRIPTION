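Package: simflow
Title: Two-Beam Structured Illumination Microscopy: Simulation,
    Reconstruction and Real-Time Streaming
Version: 0.1.0
Authors@R: person("simflow", "developers", role = c("aut", "cre"),
    email = "simflow@example.org")
Description: A desk-scale software model of a video-rate two-beam
    structured illumination microscope (SIM). Provides a virtual
    microscope that renders phantoms under sinusoidal two-beam
    illumination with an ideal incoherent optical transfer function and
    an sCMOS-like camera noise model; estimation of the illumination
    pattern wave vector, starting phase and modulation depth from raw
    nine-frame sets; generalized Wiener reconstruction with optional
    transfer-function attenuation for out-of-focus background
    suppression at twofold output sampling; a multicolor binary
    phase-grating pattern search for pixelated spatial light modulators
    with a shared Fourier-plane order-selection mask; an interleaved
    multi-camera acquisition-timing planner; and a streaming pipeline
    (wire protocol, ring buffers, affine channel registration, live
    reconstruction loop) fed by the virtual microscope or a TCP socket.
    Raw data are read and written as multipage 16-bit TIFF stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
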