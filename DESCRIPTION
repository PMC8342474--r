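Package: holopix
Title: Single-Pixel Heterodyne Holography: Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and reconstructs high-throughput single-pixel
    holography. A complex-valued object (amplitude and phase) is probed by
    binary Hadamard-like illumination patterns; a heterodyne beat signal
    encodes each projection coefficient in time, which is recovered by
    least-squares quadrature demodulation, corrected for the non-orthogonal
    binary basis using the all-ones (DC) measurement, and inverted with a
    fast Walsh-Hadamard transform, optionally compressively from a
    low-frequency-first square sampling path. Includes synthetic phantoms
    (USAF-style bar targets, quantitative phase steps, tissue-like random
    fields), image-quality metrics, and calculators for the optical system's
    resolution, field of view and space-bandwidth-time product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
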