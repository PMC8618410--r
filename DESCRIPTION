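Package: ricerisk
Title: Dietary Exposure and Health-Risk Assessment of Metals in Rice from
    In Vitro Digestion Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the human health risk of metallic and
    metalloid elements (Al, Cd, Cr, Pb, As) measured in rice before and
    after simulated gastrointestinal digestion.  Covers INFOGEST-style
    simulated digestion fluid recipes (salivary, gastric, intestinal),
    digestible/non-digestible fraction mass balance and protein
    liberation, element bioaccessibility, estimated daily intake (EDI),
    target hazard quotients (THQ/TTHQ), incremental lifetime cancer risk
    (ILCR), limit-of-quantification worst-case substitution, and the
    supporting group-comparison statistics (one-way ANOVA, Levene and
    Kolmogorov-Smirnov checks, Tukey pairwise comparisons with compact
    letter displays).  Includes a synthetic-study generator that emulates
    a variety-by-replicate measurement design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
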