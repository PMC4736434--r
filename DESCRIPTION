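Package: psychedelicr
Title: Simulation and Analysis of Selective Pure Shift 2D J-Resolved NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density-matrix simulator and processing pipeline for the
    PSYCHEDELIC family of selective pure shift 2D J-resolved 1H NMR
    experiments. Simulates the N- and R-type pulse sequences (selective
    180 degree pulses, PSYCHE double-chirp element with spatial averaging,
    phase cycling, interferogram-style chunked acquisition) on arbitrary
    scalar-coupled spin systems, processes the pseudo-3D raw data
    (chunk assembly, echo/antiecho recombination into double absorption
    lineshapes, 2D Fourier transform, 45 degree shear), and extracts
    individual 1H-1H scalar couplings from F1 doublets automatically.
    Includes an analytic weak-coupling signal model used as an
    independent oracle, canned and randomized spin-system fixtures, JSON
    and NMRPipe-format input/output, and a command-line interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
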