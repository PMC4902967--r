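Package: fisdyn
Title: Temporal Dynamics of the Inbreeding Coefficient in Partially
    Clonal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact and Monte Carlo analysis of one-locus genotype-frequency
    dynamics in finite, partially clonal diploid populations. Implements a
    state- and time-discrete Markov chain over genotypic population states
    combining k-alleles mutation, mixed clonal/sexual reproduction and
    multinomial genetic drift; exact distribution propagation, stationary
    distributions, mixing times and drift absorption times; closed-form
    maximal convergence times for reproduction and mutation and a fitted
    linear drift law, partitioning parameter space by the dominant
    evolutionary process; a single-population equilibrium reference model
    for the mean inbreeding coefficient and its inversion for the rate of
    clonality; and multilocus sampling analysis of F_IS with a
    near-fixation exclusion rule.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
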