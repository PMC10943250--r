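Package: holopolar
Title: Polarization-Interference Holographic Mapping of Birefringent Tissue
Version: 0.1.0
Authors@R:
    person("holopolar", "maintainers", email = "holopolar@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for off-axis
    polarization-interference holography of birefringent fibrillar tissue.
    Provides Stokes/Mueller/Jones algebra for linear-birefringence elements,
    a seeded phantom generator for fibrillar networks (myocardium and lung
    presets) with multiple-scattering cascades and a depolarized speckle
    background, digital-twin recording and Fourier-sideband demodulation of
    analyzer-resolved interferograms, phase-section scanning that isolates
    the single-scattering plane, row-wise Mexican-hat continuous wavelet
    markers of polarization azimuth and ellipticity maps, and
    sensitivity/specificity/balanced-accuracy diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
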