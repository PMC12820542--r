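Package: metaweight
Title: Weight Analysis and Random-Effects Meta-Analysis of Standardized
    Path Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing standardized path coefficients
    reported by primary studies of technology-acceptance models.
    Implements weight analysis (the fraction of examinations in which a
    predictor was significant, with best/promising/well-utilized
    classification), conversion of standardized beta coefficients to
    correlations and Fisher z effects, fixed-effect and
    DerSimonian-Laird random-effects pooling with Cochran Q, tau-squared
    and I-squared heterogeneity statistics, Egger regression, funnel-plot
    data and Duval-Tweedie trim-and-fill publication-bias diagnostics,
    country subgroup analysis, theory-graph synthesis of adoption models
    (TAM, UTAUT, HBM/PMT, TTF, PCT, TPB, DOI), and a synthetic-corpus
    generator emulating the random-effects data-generating process for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
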