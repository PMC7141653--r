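Package: ioirhythm
Title: Rhythm and Periodicity Analysis of Animal Acoustic Signal Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies periodicity in sequences of acoustic-signal element
    onsets (bat calls, whale click trains, bird song and similar point
    processes). Implements inter-onset-interval (IOI) statistics with an
    unbiased coefficient of variation, the normalized Pairwise Variability
    Index (nPVI), beat detection by Fourier analysis of a binary point
    process with a DC-offset-normalized goodness of fit (nGOF), a
    generate-and-test search for the best isochronous beat scored by a
    frequency-normalized root-mean-square deviation (FRMSD), recurrence
    matrices of IOI differences, and agglomerative clustering of beat
    frequencies within individuals. A fitting front end, beat_fit(), returns
    a classed model object with the usual print, summary, coef, plot,
    predict and residuals methods; synthetic onset-sequence generators and a
    rule-based method-selection report support end-to-end analyses without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
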