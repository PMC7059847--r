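Package: avsync
Title: Audio-Based Synchronization of Multi-Camera Recordings and
    Facial-Expression Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporally aligning video or audio recordings to a
    reference audio segment, as needed when head-mounted or otherwise
    untriggered cameras record an experiment. Offsets are found by a
    sliding-window Pearson correlation search or by FFT cross-correlation,
    and recordings can be trimmed accordingly. The package also provides
    the downstream statistics used with such recordings: agreement between
    manual and automatic offsets, event-locked comparisons of facial
    expression evidence, and intersubject correlation (ISC) of expression
    time series with Fisher r-to-z inference. Seeded generators produce
    synthetic sync-tune and expression fixtures so the whole pipeline can
    be exercised without any media downloads.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
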