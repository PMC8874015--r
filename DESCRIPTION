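Package: tsnets
Title: Network Analysis of Nonlinear Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts univariate or multivariate time series into
    state-space networks -- epsilon-recurrence networks, natural and
    horizontal visibility graphs, and ordinal partition networks -- and
    computes the dynamical and information-theoretic measures defined on
    them: sample entropy from recurrence densities, degree-distribution
    entropy, permutation entropy, determinism and degeneracy of the
    state-transition structure, entropy production, and constrained
    random-walk surrogate series. Includes embedding-parameter selection
    (autocorrelation and auto-mutual-information lag criteria,
    degree-variance and permutation-entropy dimension criteria), shared
    graph descriptors, community detection and macro-state
    renormalization, a synthetic-signal generator for reference dynamics
    (chaotic flows, maps, colored noise), and plain-text readers/writers
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
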