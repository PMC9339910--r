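Package: polstim
Title: Dual-Projector Polarised-Light Stimulation and Analysis for Insect Vision
Version: 0.1.0
Authors@R:
    person("Polstim", "Developers", email = "polstim@example.org", role = c("aut", "cre"))
Description: Tools for generating and analysing moving patterns of linearly
    polarised light produced by a dual digital-light-processing (DLP) projector
    display. Encodes intensity and degree-of-linear-polarisation (DoLP)
    commands into paired 4-bit greyscale frames, packs them into 24-bit video
    frames for high-frame-rate presentation, models and calibrates the
    polariser-angle-dependent luminance of projector LEDs, computes Stokes
    parameters, angle of polarisation (AoP) and DoLP maps from four-angle
    imaging polarimetry, maps photoreceptor receptive fields and polarisation
    tuning from intracellular recordings, and estimates local preferred
    direction and local motion sensitivity of motion-sensitive interneurons
    from spike trains recorded during circular-dot stimulation. Built-in
    simulators of photodiodes, polarisation-sensitive photoreceptors and a
    direction-tuned Poisson spiking neuron provide ground truth for
    end-to-end validation without hardware or animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
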