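Package: corticat
Title: Recurrent Cortical-Column Model of Unsupervised Category and
    Subcategory Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a three-layer recurrent cortical-column network
    that learns visual categories and refines them into subcategories
    without supervision. Feedforward (instar, Oja-type) weights acquire
    prototype receptive fields, feedback (outstar) weights acquire the
    expected average input of each category cell, and a rectified residual
    between the current input and the winning cell's top-down prediction
    multiplicatively amplifies the unexplained part of the stimulus,
    recruiting fresh cells for subcategory representations. Includes a
    synthetic pictogram stimulus generator (faces and barred squares),
    divisive pool normalization solved at steady state, presets that
    reproduce four training protocols, post-hoc classification of cells
    into overall-category, subcategory and unused roles, tidy accessors
    and ggplot2 visualizations.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
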