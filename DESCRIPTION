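Package: kmerbin
Title: Minimizer Orderings, Super-Mer Binning and k-Mer Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splits DNA sequencing reads into super-mers (maximal substrings
    whose k-mers share one minimizer) under six minimizer orderings --
    lexicographic, KMC2-style signature, seeded random, frequency-sampled,
    and universal-hitting-set restrictions of these (universal lexicographic,
    universal random, and the universal frequency ordering) -- then counts
    k-mers per bin and reports bin-distribution statistics (bin sizes,
    max/mean ratio, average super-mer length, and the share of k-mer mass in
    the largest 0.5% of bins) used to compare orderings for load balance and
    compactness. Includes a universal hitting set loader/verifier/generator,
    a seeded synthetic read generator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
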