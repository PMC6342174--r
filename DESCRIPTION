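Package: chromcurate
Title: Curation and Visualization of Plant Chromosome-Count Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate heterogeneous plant chromosome-count records of
    the kind exported from the Chromosome Counts Database (CCDB). Cytological
    notation (bivalent/univalent/multivalent configurations, B chromosomes,
    supernumerary ranges, approximate and fragment annotations) is parsed
    into clean integer chromosome counts with full provenance. The package
    tabulates intra- and interspecific count variation, infers ploidy levels
    against a user-supplied base chromosome number, builds stacked-bar and
    heatmap plot data in the style used for karyotype summaries, and ships a
    seeded synthetic record generator so the whole pipeline can be exercised
    end-to-end without any database download.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
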