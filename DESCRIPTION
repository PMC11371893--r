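Package: mlrqca
Title: Lesion Quantification and Risk Analysis for 3D Quantitative Coronary Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of mild coronary lesions on
    arc-length-parameterized lumen area profiles from three-dimensional
    quantitative coronary angiography (3D-QCA). Fits an interpolated
    "healthy" reference line by iteratively trimmed regression in the
    equivalent-diameter domain, locates lesion edges at the crossings of
    the measured and reference area functions, and computes the minimum
    lumen ratio MLR = MLA/PROXA together with the companion descriptors
    (MLA, PROXA, DISTA, LSL, PLSL, LLR, percent area stenosis) and the
    translesional pressure-ratio gradient (delta-vFFR) from a supplied
    vFFR pullback. Includes a fully synthetic cohort generator with
    quantile-matched split-normal marginals coupled by a Gaussian copula,
    whose vessels round-trip through the measurement stack, and a
    statistics pipeline covering Mann-Whitney group comparisons with
    Bonferroni adjustment, Spearman correlation, ROC/AUC with DeLong
    inference, Youden cutoffs, and Kaplan-Meier / Cox hazard-ratio
    analysis of dichotomized lesion metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
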