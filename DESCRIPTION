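Package: waspdrive
Title: Gene-Drive Population Dynamics for Haplodiploid Social Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates CRISPR homing gene drives targeting spermatogenesis in
    haplodiploid social wasps (Vespula spp.). Implements a deterministic
    annual recursion over six queen classes (queen genotype by effective mate
    class), a stochastic integer-state twin capturing demographic noise and
    gene drift, timed management interventions (carrier-queen releases and
    population culls), and threshold and phase-scan analyses of suppression
    and eradication outcomes. Trajectories and scans are returned as tibbles
    with tidy(), glance() and autoplot() methods.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
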