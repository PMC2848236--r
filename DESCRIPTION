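Package: nacorrect
Title: Natural Abundance Correction of Isotopically Resolved
    Isotopologue Intensities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes (and forward-models) the contribution of 13C and 15N
    natural abundance from isotopically resolved isotopologue intensity
    sets, as measured in stable-isotope-tracing experiments on
    ultra-high-resolution mass spectrometers (FT-ICR-MS).  Because every
    isotopologue peak is resolved and identified, the correction is
    analytically exact: each observed peak is a known binomial mixture of
    tracer-labeled species, and the mixture is inverted by a sequential
    (triangular) solve.  An iterative algorithm layers missing-peak
    supplementation, negative flattening and renormalization on top of
    the exact solve, and reports a residual usable as an independent
    quality-control signal.  Single-label (13C or 15N) and dual-label
    (13C plus 15N) data are supported, in IEEE double precision or an
    extended 80-bit precision mode for very large molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
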