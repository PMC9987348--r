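Package: zipfcds
Title: Zipf-Mandelbrot Analysis of Word Frequencies in Child-Directed Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying word rank-frequency distributions in
    child-directed speech. Reads CHAT transcripts and precomputed frequency
    lists, builds rank-frequency tables with randomised tie-breaking, fits the
    Zipf-Mandelbrot law by maximum likelihood, evaluates goodness of fit by
    correlating observed and expected frequencies, and provides split-half
    validation, discrete power-law fitting with a Kolmogorov-Smirnov threshold
    search, conversationally continuous subsampling, sample-size stability
    curves, age-binned developmental analyses with mixed-effect trend models,
    per part-of-speech analyses, and a fully seeded synthetic corpus generator
    used for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
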