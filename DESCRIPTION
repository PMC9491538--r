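Package: glottikit
Title: Glottis Segmentation Assessment for Laryngeal High-Speed Videoendoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term assessment of automatic glottis segmentation
    in laryngeal high-speed videoendoscopy (HSV). Provides a synthetic phantom
    generator with ground-truth masks and analytic glottal area waveforms
    (GAW), lossy and lossless video round-tripping with compression-aware
    image-quality metrics (dynamic range, MSE, PSNR, SSIM and a blind NIQE
    score), a small encoder-decoder glottis segmenter with GAW extraction,
    segmentation evaluation (IoU, boundary IoU, Dice, pixel accuracy) with
    automated artifact detection, and a continual-learning harness with
    fixed-time and fixed-quantity pseudo-label fine-tuning schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    EBImage,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: SVT-AV1 (SvtAv1EncApp) and dav1d on the PATH for the
    lossy video dialect
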