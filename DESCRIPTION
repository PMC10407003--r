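Package: bodyregions
Title: Body Region Classification of CT and MRI Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for automatic body-region labeling of
    cross-sectional imaging series. Provides the 17-class (CT) and 18-class
    (MRI) body-region vocabularies with their anatomical landmark intervals,
    a patient/study/series/image data model with the standard series- and
    image-level inclusion filters, thin 3D bounding-box ground-truth
    propagation in patient coordinates, the image preprocessing chain
    (intensity clipping, normalization, channel replication, aspect-preserving
    pad-and-resize to 224x224), a compact trainable multi-class slice
    classifier with spatial augmentation and active-learning uncertainty
    ranking, series-level rule-based post-processing (transitional-class
    merging, breast-series rule, outlier removal, moving-average smoothing,
    confidence thresholding), and a spatially aware bootstrap evaluation
    (weighted F1/sensitivity/specificity with minimum slice spacing and
    one-series-per-study resampling, plus chi-squared/Cramer's V association
    statistics). A seedable geometric phantom generator exercises the whole
    pipeline end to end without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
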