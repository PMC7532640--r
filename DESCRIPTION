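Package: lesionmorph
Title: Morphological and Texture Features of Contoured Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eleven morphological and grey level gradient co-occurrence
    matrix (GLGCM) texture features from grey-scale ultrasound images with
    manually contoured lesion boundaries: circularity, height-to-width ratio,
    margin spicules, margin coarseness, margin indistinctness, margin
    lobulation, internal calcification count, energy, entropy, grey mean, and
    the angle between the lesion long axis and the skin line. Includes a
    seeded speckle-phantom generator with planted ground truth (boundary
    harmonics, orientation, calcifications, margin blur), two-group
    comparison of feature tables by independent-samples t-tests, and a batch
    extraction pipeline over image/contour manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
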