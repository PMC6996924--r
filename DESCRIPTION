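Package: hxtools
Title: Hydrogen-Exchange Mass Spectrometry Uptake and EX1 Bimodal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hydrogen/deuterium-exchange mass spectrometry (HX-MS)
    data at the peptic-peptide level: monoisotopic mass and theoretical
    isotope-envelope computation, sequence-coverage maps, centroid-based
    deuterium uptake with back-exchange correction against fully deuterated
    controls, condition difference profiles, and deconvolution of bimodal
    (EX1-regime) isotope clusters by a global two-Gaussian fit with
    extraction of subpopulation fractions and transition rate constants
    (k_trans) from one-phase association fits. Includes a synthetic-data
    generator for EX1/EX2 exchange kinetics with back-exchange and noise,
    plus fitting of ancillary biophysical measurements: fluorescence
    anisotropy with Hill binding curves, FRET association kinetics with
    initial velocities, biexponential bio-layer interferometry dissociation,
    and differential scanning fluorimetry melting temperatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
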