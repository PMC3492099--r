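Package: sitelogic
Title: Interpretable Logic-Minimization Rules for Functional-Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts small sets of human-readable boolean rules that predict
    functional sites in molecular sequences, such as transcription-factor
    binding sites in DNA and O-glycosylation sites in proteins. Sequence
    windows are one-hot encoded into binary variables, the most informative
    variables are selected by recursive feature elimination with a linear
    support vector machine, and the resulting partially-specified boolean
    function is minimized exactly (Quine-McCluskey with a minimum-cover
    search) or heuristically (an ESPRESSO-style expand/irredundant/reduce
    loop with don't-cares). Minimized rules are scored by their popularity
    in the training set and used to scan sequences, with tunable
    sensitivity/precision trade-offs. Includes seeded synthetic-data
    generators for motif-implanted DNA and glycosylation-style protein
    windows, Berkeley PLA input/output, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
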