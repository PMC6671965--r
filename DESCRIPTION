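Package: heiderdyn
Title: Structural Balance Dynamics on Directed Signed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the continuous-time dynamics of interpersonal relations
    on fully connected directed signed networks, in which each directed
    relation evolves under the influence of the remaining actors and the
    system generically freezes at a +/-1 corner state.  Provides the
    self-evaluation ("looking-glass self") index of each actor, an
    equitable-partition classifier that reduces a frozen sign matrix to an
    unlabeled graph of node classes, closed-form stability analysis of the
    recurring two-, three- and four-class archetypes, Monte-Carlo ensemble
    experiments with frequency statistics of terminal class graphs, and
    readers for sociometric valued matrices (UCINET DL and CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
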