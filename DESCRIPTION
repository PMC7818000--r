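Package: paraxial
Title: Paraxial Ray Tracing and Aperture Analysis for Optical System Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models optical imaging paths in the paraxial (ABCD ray-transfer
    matrix) approximation, with finite element apertures. Detects the aperture
    and field stops of a sequential system, solves the axial, marginal, chief
    and principal rays, computes the field of view, numerical aperture and
    Lagrange invariant, finds conjugate planes, and diagnoses vignetting by
    decomposing Monte-Carlo ray ensembles onto the principal/axial ray basis.
    Includes Gaussian-beam q-parameter propagation through the same matrices,
    programmatic builders for standard microscopy layouts (confocal detection
    and scan paths, Koehler illumination, widefield relays), a declarative YAML
    system description format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
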