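Package: mdbs
Title: Multialternative Decision by Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sequential-sampling model of multialternative, multiattribute
    choice in which evidence units arise from similarity-weighted, soft
    ordinal comparisons of attribute values held in working memory.
    Provides closed-form and simulation-based choice probabilities under a
    relative stopping rule, a battery of context-effect scenarios
    (attraction, compromise, similarity, attribute balance, background
    contrast, phantom decoys, intransitive cycles, and more), packaged
    attribute-value fixtures, decoy constructors, synthetic choice-data
    generation, and maximum-likelihood parameter fitting with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
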