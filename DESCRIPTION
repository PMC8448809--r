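Package: braincons
Title: Robust Consensus Braingraphs from Repeated Probabilistic Tractography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds robust structural connectomes (braingraphs) from repeated runs
    of probabilistic tractography. Provides GraphML readers and writers for
    anatomically labeled brain networks carrying fiber-count, mean streamline
    length and mean fractional anisotropy edge weights; consensus construction by
    edge intersection across runs with min/max-trimmed averaging of fiber counts;
    multi-resolution coarsening by vertex contraction along a parcellation
    hierarchy; a coefficient-of-variation repetition sweep for choosing the number
    of tractography repetitions; and a stochastic simulator of tractography output
    for testing without MRI data. A command-line interface exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
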