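Package: ethnosurvey
Title: Quantitative Ethnobotany of the Miracle Plant: Use Values, Knowledge
    Transmission and Cultivation Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative ethnobotanical surveys of
    Synsepalum dulcificum (the miracle plant) in West Africa. Implements
    use-value indices (Phillips & Gentry), the informant agreement ratio,
    the KMTO (Kernel-Mutation-Type-Order) classification of traditional
    knowledge acquisition paths, a contingency-table and count-regression
    statistical harness with small-sample and overdispersion fallbacks,
    CART-style classification and regression trees with cost-complexity
    pruning for cultivation-driver analysis, and a seeded synthetic survey
    generator that emulates the demographic and use-report structure of a
    510-respondent, nine-group survey so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
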