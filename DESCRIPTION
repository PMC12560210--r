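Package: ktptx
Title: kT-Point Parallel-Transmit Pulse Design and B1+ Shimming at 7 T
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and design tools for static and dynamic
    parallel-transmit (pTx) excitation of large abdominal targets at
    ultrahigh field. Synthesizes channel-wise complex B1+ maps for a
    remote three-ring 32-element transmit array, estimates relative B1+
    maps from a small-flip-angle calibration scheme, designs phase-only
    and magnitude-plus-phase static shims and kT-point pulses by
    regularized magnitude least squares in the small-tip-angle
    approximation, and reproduces L-curve, channel-count and relative
    local-SAR analyses of the flip-angle homogeneity / RF power
    trade-off, validated against a brute-force Bloch rotation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
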