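Package: shgbof
Title: Patch-Based GLCM Texture Analysis and Bag-of-Features
    Classification for Second Harmonic Generation Microscopy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry for osteochondral second harmonic
    generation (SHG) microscopy images. Extracts Haralick texture
    parameters (correlation, angular second moment, contrast, inverse
    difference moment, entropy, sum entropy, sum average, sum variance)
    from gray-level co-occurrence matrices computed on small regions of
    interest, assembles 352-dimensional patch descriptors from per-patch
    parameter histograms, and classifies whole images with a
    bag-of-visual-words pipeline (k-means codebook, nearest-word term
    vectors, linear support-vector classifiers with one-vs-one
    error-correcting output codes for the ternary task). Includes a
    synthetic SHG texture generator for cartilage-, bone- and
    fibrous-cartilage-like images, minimal grayscale TIFF/PGM input and
    output, 12-bit to 8-bit conversion, signal-based image and patch
    filtering, multi-run confusion-matrix evaluation, parameter sweeps,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
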