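Package: fuzzymrf
Title: Fuzzy Markov Random Field Segmentation of Lung Tumors on PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic lung tumor segmentation on co-registered PET/CT
    volumes with a fuzzy Markov random field model. CT intensity and
    PET standardized uptake value (SUV) are fused through a min/max
    joint class-conditional likelihood, combined with a Gibbs smoothness
    prior over a 5x5x3 voxel neighborhood, and the per-voxel tumor
    membership field is estimated by projected gradient ascent on the
    resulting MAP objective. Includes fuzzy C-means based parameter
    estimation, a synthetic PET/CT phantom generator with known ground
    truth for end-to-end validation, Dice-coefficient evaluation over
    phantom replicates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml,
    optparse,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
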