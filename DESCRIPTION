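Package: rootzone
Title: Threonine-Gated Root Meristem Growth and Cell-Length Zonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the coupling between free threonine (Thr) metabolism and
    root apical meristem (RAM) organisation in Arabidopsis thaliana. Provides
    steady-state models of the free Thr, glycine and isoleucine distribution
    along the root axis driven by opposing linear expression gradients of the
    threonine synthases MTO2 and TSY2 (with THA1/2 and OMR1 catabolism and
    Ile feedback in the extended variant); a deterministic lattice simulator
    of root growth in which cell division is gated by local free Thr,
    reproducing indeterminate wild-type and determinate mto2-2 mutant growth;
    multiple-structural-change (MSC) zonation of cortical cell-length
    profiles by exact dynamic-programming breakpoint placement with BIC model
    selection and the f/h minimal-segment rule; and a synthetic cell-length
    profile generator for end-to-end testing without microscopy data.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
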