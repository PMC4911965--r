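Package: chodetect
Title: Task-Based CT Image Quality Assessment with a Channelised Hotelling Observer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for task-based assessment of low-contrast detectability in
    computed tomography. Implements a channelised Hotelling observer (CHO)
    with dense difference-of-Gaussian frequency channels, four-alternative
    forced-choice (4-AFC) detection experiments scored as percent correct,
    and bootstrap confidence intervals, together with a synthetic phantom
    module that generates signal-present and signal-absent regions of
    interest across a factorial grid of dose, reconstruction strength,
    contrast and target size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
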