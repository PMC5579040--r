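Package: clsense
Title: Analysis of Ratiometric Chloride-Indicator Imaging in Brain Slices
Version: 0.1.0
Authors@R: person("clsense", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing recordings from genetically encoded
    ratiometric chloride indicators (CFP/Cl-sensitive-YFP fusions) in acute
    brain slices. Converts two-channel ROI fluorescence time series into
    corrected chloride-proxy ratios (background subtraction, single-exponential
    photoinactivation drift correction, exposure normalisation), fits and
    inverts the four-parameter sigmoid calibration relating the ratio to
    intracellular chloride concentration, quantifies bath-drug and agonist-puff
    responses, performs cluster-robust inference with generalized estimating
    equations (slices as clusters), estimates GABA-A reversal potentials from
    voltage-ramp current pairs, and simulates complete synthetic datasets with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
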