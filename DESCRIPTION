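Package: crowndetect
Title: Single-Species Tree Detection and Crown-Object Mapping from
    Hyperspectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of focal canopy tree species in hyperspectral
    reflectance imagery of diverse closed-canopy forests. Implements
    one-against-all binary and biased (positive-unlabeled) support vector
    machine detectors with crown-level cross-validation and the r^2/P[f(x)=1]
    tuning criterion, rule-based fusion of single-species detectors into a
    multi-species pixel classifier with a balanced tie-breaking SVM,
    morphological contextual filtering (pixel quartering, 3x3 opening-closing)
    and side-adjacent connected-component extraction of crown objects, and a
    synthetic hyperspectral forest-scene generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
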