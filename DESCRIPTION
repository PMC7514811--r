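Package: qwkernel
Title: Graph Similarity Kernels from Continuous-Time Quantum Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the similarity between two graphs, directed or
    undirected, by simulating a pair of interference-engineered
    continuous-time quantum walks on their merged graph and computing the
    quantum Jensen-Shannon divergence between the infinite-time average
    density matrices of the two walks.  Supports adjacency, Laplacian and
    normalised-Laplacian Hamiltonians, Chung's directed Laplacians for
    directed graphs, heat- and wave-kernel node signatures for weighted
    merging, a provably positive-definite kernel variant with a
    closed-form spectral computation, a measurement-sampling estimator of
    the kernel, and a support-vector-machine cross-validation harness for
    graph classification with precomputed Gram matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    kernlab,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
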