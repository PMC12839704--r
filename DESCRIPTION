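Package: spiroqc
Title: Intelligent Quality Control for Spirometry Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated acceptability assessment of spirometry manoeuvres from
    report pages. Builds a graphical construct that combines the binarized
    flow-volume and volume-time curves with patient demographics (sex, age,
    BMI) encoded as grayscale frame sections, classifies the manoeuvre as
    acceptable or unacceptable with a compact convolutional network, selects
    the decision threshold by maximizing the Matthews correlation coefficient,
    and explains predictions with gradient-weighted class-activation (Grad-CAM)
    heatmaps. Includes a synthetic report simulator (forced-expiration
    manoeuvres with cough, early-termination, submaximal-effort and
    extra-breath artifacts rendered as report pages) so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    pracma,
    png,
    tiff,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
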