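Package: holopsr
Title: Lensless In-Line Holography with Multi-Frame Pixel Super-Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs high-resolution in-line holograms from stacks of
    low-resolution frames acquired under small irregular light-source
    displacements, as in portable lensless wide-field microscopy. Frames
    are pre-aligned by a feature-based registration pipeline, refined to
    sub-pixel accuracy by minimizing a variational energy (data fidelity
    plus a sum-modified-Laplacian sharpness term) with a continuous ant
    colony optimizer, and fused onto a finer pixel grid. Object-plane
    morphology is then recovered by band-limited angular-spectrum
    back-propagation. A synthetic acquisition simulator (complex
    transmittance scenes, forward diffraction, sub-pixel displacement
    grids, detector downsampling, quantization and noise) provides ground
    truth for end-to-end validation, and diagnostic metrics (focus
    measures, Prewitt compass gradients, fringe-cycle counting, two-point
    resolution tests) quantify the resolution gain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
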