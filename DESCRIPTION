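Package: tumorniche
Title: Niche Construction, Clonal Competition and the Ecology of Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and hybrid stochastic simulation of a four-clone
    Lotka-Volterra model of tumor niche construction, in which producer cells
    pay a growth-rate cost to secrete a shared resource that raises the
    carrying capacity of the primary tumor, and secondary producers prepare a
    distant pre-metastatic niche. Provides the governing ordinary
    differential equations under three interclonal competition structures,
    fast/slow (quasi-equilibrium) reduction of the resource dynamics,
    analytic and numerical invasion and stability analysis of rare
    metastasis-promoting mutants, and a seeded mutation-arrival ensemble
    that exposes the trade-off between the arrival of metastasis-promoting
    mutations and their ability to invade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
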