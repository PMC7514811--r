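# Small named fixtures used across the suite, built in code.

path3 <- function() graph_from_edges(3, c(1, 2), c(2, 3))
k3 <- function() graph_from_edges(3, c(1, 1, 2), c(2, 3, 3))
cycle4 <- function() graph_from_edges(4, c(1, 2, 3, 4), c(2, 3, 4, 1))
star4 <- function() graph_from_edges(4, c(1, 1, 1), c(2, 3, 4))
single_edge <- function() graph_from_edges(2, 1, 2)
dir_cycle3 <- function() graph_from_edges(3, c(1, 2, 3), c(2, 3, 1),
                                          directed = TRUE)
bidir_pair <- function() graph_from_adjacency(rbind(c(0, 1), c(1, 0)),
                                              directed = TRUE)

# connected, non-regular ER graph (regular draws are rejected so the
# constrained initial state always exists)
nonregular_er <- function(n, p, seed) {
  for (k in 0:50) {
    g <- er_graph(n, p, seed = seed + 1000 * k, require_connected = TRUE)
    if (length(unique(degrees(g))) > 1) return(g)
  }
  stop("no non-regular draw found")
}

expect_symmetric <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol)
}

new_energy_dist_for_test <- function(support, probs) {
  qwkernel:::new_energy_dist(support, probs)
}

with_seed_for_test <- function(seed, code) {
  qwkernel:::with_seed(seed, code)
}
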