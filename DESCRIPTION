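Package: gameticsel
Title: Gametic Selection, Mating Systems, and the Evolution of Selfing
    and Polyandry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the two-way interaction between competition among male
    gametes (pollen or sperm) and mating systems in hermaphrodites.
    Provides exact deterministic two-locus recursions for a selected locus
    linked to a mating-system modifier, weak-selection approximations for
    invasion conditions, equilibrium allele frequencies at
    mutation-selection balance and under balancing selection, modifier
    spread rates along the monandry-polyandry and selfing-outcrossing
    axes, genome-wide mutation load and inbreeding depression, and an
    individual-based multilocus Wright-Fisher simulator with explicit
    gamete competition.  The three layers are cross-validated against
    each other.
License: MIT + file LICENSE
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
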