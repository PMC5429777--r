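Package: sparsewell
Title: Sparse-Coding Early Warning for Bacterial Contamination in Water Wells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Early-warning analysis of sparse, irregularly sampled fecal
    coliform count series from drinking-water wells. Counts are placed on a
    daily calendar grid with fictitious zeroes, cut into 90-day windows,
    transformed with an unnormalized type-II discrete cosine transform, and
    reduced to a fixed random subset of spectral coefficients. Contamination
    risk is classified with a soft-margin support vector machine and a
    minimum-volume-ellipsoid novelty detector (Khachiyan's algorithm), with a
    delay-embedded neural network baseline. The package also provides a
    signal-energy moving-window alarm with Pareto-frontier tuning,
    basis-pursuit (l1) reconstruction of sparse series from partial DCT
    measurements, a synthetic well generator, and end-to-end evaluation of
    warning lead time and false-alarm rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quadprog,
    nnet,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
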