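Package: spinalign
Title: Automated Spinopelvic Parameter Measurement from Sagittal Spine Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures the thirteen standard sagittal alignment and spinopelvic
    parameters (C2/T1/L1 incidence and slope, cervical and lumbar lordosis,
    thoracic kyphosis, sacral slope, pelvic tilt, pelvic incidence, and the
    C2-7 and C7 sagittal vertical axes) from labeled instance segmentations of
    vertebral bodies, sacrum, and femoral heads on whole-spine lateral
    radiographs. Masks are reduced to anatomical landmark points by polygon
    approximation and endplate corner extraction, with an IoU-based quality
    gate. Includes a parametric synthetic spine generator with analytically
    known ground truth, agreement statistics for rater studies (ICC(2,1) with
    confidence intervals, Bland-Altman limits of agreement, absolute-error
    summaries), COCO-style annotation input/output, overlay rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
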