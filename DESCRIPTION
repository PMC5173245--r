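Package: tpstereo
Title: Two-Photon Laser Scanning Stereomicroscopy: Simulation and Depth
    Reconstruction
Version: 0.1.0
Authors@R:
    person("TPLSSM", "Maintainers", email = "tpstereo@example.org",
           role = c("aut", "cre"))
Description: Simulates extended-depth-of-field two-photon stereomicroscopy
    with tilted Bessel-Gauss beams and recovers per-object depth from the
    resulting stereo image pairs.  Includes a scalar-diffraction
    (angular-spectrum) model of annular-pupil excitation, a stereo-scanner
    waveform and volume-rate timing model, a synthetic bead-phantom engine
    with a shear-projection forward imaging model, interlaced-frame to
    stereo-pair conversion (including anaglyph export), a feature-based
    correspondence pipeline (low-pass filter, Richardson-Lucy deconvolution,
    circular Hough transform, energy/epipolar cost matching, triangulation),
    depth-accuracy evaluation against ground truth, and simple 3D
    nearest-neighbour track linking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
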