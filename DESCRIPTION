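Package: netconstr
Title: Parallel Construction Kernel for Spiking Neuronal Networks
Version: 0.1.0
Authors@R:
    person("netconstr", "developers", email = "netconstr@example.org",
           role = c("aut", "cre"))
Description: Models the network-construction phase of parallel spiking
    neuronal network simulators: round-robin distribution of nodes over
    virtual processes, per-virtual-process random streams, an adaptive
    per-source connector hierarchy with a sparse source table, fixed
    in-degree and all-to-all wiring in two loop orders, closed-form and
    Monte-Carlo predictors for connector sizes and memory-allocation
    counts, an abstract allocator-contention model, and a minimal
    leaky integrate-and-fire dynamics loop over the constructed
    adjacency. Includes a command-line front end and a builder for the
    balanced random network benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
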