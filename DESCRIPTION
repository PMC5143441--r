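Package: hasim
Title: Hybrid Angular Spectrum Simulation and Phase Aberration Correction
    for Focused Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state full-wave simulation of therapeutic focused
    ultrasound through voxelized heterogeneous media using the hybrid
    angular spectrum (HAS) method, which alternates per-voxel space-domain
    phase/attenuation steps with spectral-domain diffraction steps slice by
    slice.  Provides simulation-based phase aberration correction for
    phased-array transducers (per-element zero-phase simulations, conjugate
    phases at arbitrary treatment locations), builders for voxelized
    acoustic models (homogeneous water, a 3D-printable random-relief
    aberrator plate, CT Hounsfield-unit derived skull models, synthetic
    skull-like phantoms), and treatment-analysis procedures:
    steering-improvement maps, translational misregistration sensitivity
    maps, and phasor autocorrelation of accumulated phase-length maps with
    contour-area summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
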