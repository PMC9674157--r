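Package: radpoi
Title: Predicting Age at Premature Ovarian Insufficiency After Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the age at premature ovarian insufficiency (POI) for
    female cancer patients from age at radiotherapy and the dose received by
    the least-affected ovary. Combines the Wallace-Kelsey asymmetric
    double-Gaussian-cumulative model of the age-related decline in non-growing
    follicles with a single-hit exponential radiation survival model (LD50 = 2
    Gy), inverts the decline curve to an equivalent chronologic age after
    irradiation, and ages the survivor forward to the 1,000-follicle menopause
    threshold. Provides prediction windows over dose triplets and z-score
    bands, mean and effective sterilizing dose curves, photon/proton treatment
    plan comparison from per-ovary dose summaries, calculator-style charts,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
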