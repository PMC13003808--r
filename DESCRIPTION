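Package: wmlatent
Title: Latent Variable Models of White Matter Microstructure and Fluid Intelligence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confirmatory factor models for tract-average markers of white
    matter microstructure (fractional anisotropy, intra-neurite volume
    fraction, magnetization transfer ratio) over ten functional tract
    clusters of the HCP-1065 atlas. Provides a full-information maximum
    likelihood estimation engine for structural equation models with
    planned missingness, a declarative library of twelve competing
    measurement architectures (single-factor, bifactor, hierarchical and
    hemisphere-bifactor variants), joint multi-marker models with latent
    regression of fluid intelligence, AIC/Akaike-weight model comparison,
    RMSEA-based power analysis, preprocessing (tract-to-cluster averaging,
    outlier screening, two-sample z-standardization, split-half
    reliability), and a two-site synthetic cohort generator for end-to-end
    testing without access to the original MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
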