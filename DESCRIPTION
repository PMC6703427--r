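Package: alkanogen
Title: Stoichiometry and Bioenergetics of Methanogenic Alkane Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bioenergetic analysis of anaerobic long-chain
    alkane degradation by archaea that disproportionate alkanes to methane
    and carbon dioxide in a single cell. Generates balanced reactions for
    the catabolic fates of an n-alkane (complete oxidation to H2,
    acetogenic oxidation, and methanogenic disproportionation) and for the
    three half-steps of the proposed pathway (alkane oxidation to
    H4MPT-bound methyl groups, methyl reduction to methane, and CO2
    reduction); keeps an exact electron ledger over the pathway; evaluates
    standard, pH-transformed and in-situ Gibbs energies from a shipped
    formation-energy table; screens thermodynamic feasibility over
    synthetic deep-sea seep condition sets; and implements the CARD-FISH
    cell-enumeration arithmetic (grid counts to cells per ml, spherical
    aggregate cell estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
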