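test_that("graph construction validates its invariants", {
  expect_error(graph_from_adjacency(matrix(c(0, -1, -1, 0), 2)),
               "nonnegative")
  expect_error(graph_from_adjacency(diag(2)), "diagonal")
  expect_error(graph_from_adjacency(rbind(c(0, 1), c(0, 0)),
                                    directed = FALSE), "symmetric")
  g <- graph_from_adjacency(rbind(c(0, 1), c(0, 0)))
  expect_true(g$directed)  # asymmetry inferred
  expect_error(graph_from_edges(3, 1, 1), "self-loops")
})

test_that("degrees match hand-computed examples", {
  expect_equal(degrees(path3(), "total_undirected"), c(1, 2, 1))
  expect_equal(degrees(dir_cycle3(), "out"), c(1, 1, 1))
  expect_equal(degrees(dir_cycle3(), "in"), c(1, 1, 1))
  expect_equal(degrees(dir_cycle3(), "total_directed"), c(2, 2, 2))
  isolated <- graph_from_adjacency(matrix(0, 1, 1))
  expect_equal(degrees(isolated), 0)
  # directed graphs default to out-degree, undirected to total
  d <- graph_from_edges(3, 1, 2, directed = TRUE)
  expect_equal(degrees(d), c(1, 0, 0))
})

test_that("laplacian matches closed forms and rejects directed input", {
  expect_equal(laplacian(single_edge())$matrix, rbind(c(1, -1), c(-1, 1)))
  expect_equal(sort(eigen(laplacian(k3())$matrix, symmetric = TRUE,
                          only.values = TRUE)$values),
               c(0, 3, 3), tolerance = 1e-12)
  empty <- graph_from_adjacency(matrix(0, 4, 4), directed = FALSE)
  expect_equal(laplacian(empty)$matrix, matrix(0, 4, 4))
  expect_error(laplacian(dir_cycle3()), "directed_laplacian")
})

test_that("normalised laplacian is symmetric with spectrum in [0, 2]", {
  NL <- normalised_laplacian(single_edge())$matrix
  expect_equal(NL, rbind(c(1, -1), c(-1, 1)))
  expect_equal(sort(eigen(NL, only.values = TRUE)$values), c(0, 2))
  expect_equal(sort(eigen(normalised_laplacian(k3())$matrix,
                          only.values = TRUE)$values),
               c(0, 1.5, 1.5), tolerance = 1e-12)
  # isolated node: zero row/column by convention
  g <- graph_from_edges(3, 1, 2)
  NL3 <- normalised_laplacian(g)$matrix
  expect_equal(NL3[3, ], c(0, 0, 0))
  expect_equal(NL3[, 3], c(0, 0, 0))
})

test_that("transition matrix is row-stochastic with zero sink rows", {
  expect_equal(transition_matrix(dir_cycle3()),
               rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  fork <- graph_from_edges(3, c(1, 1), c(2, 3), directed = TRUE)
  M <- transition_matrix(fork)
  expect_equal(M[1, ], c(0, 0.5, 0.5))
  expect_equal(M[2, ], c(0, 0, 0))  # sink convention
})

test_that("stationary distribution fixes the chain and demands strong connectivity", {
  expect_equal(stationary_distribution(transition_matrix(dir_cycle3())),
               rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(stationary_distribution(transition_matrix(bidir_pair())),
               c(0.5, 0.5), tolerance = 1e-10)
  two_cycles <- graph_from_edges(4, c(1, 2, 3, 4), c(2, 1, 4, 3),
                                 directed = TRUE)
  expect_error(stationary_distribution(transition_matrix(two_cycles)),
               "strongly connected")
  # residual check on a random strongly connected chain
  M <- transition_matrix(strongly_connected_digraph(9, 0.3, seed = 4))
  pi_v <- stationary_distribution(M)
  expect_gte(min(pi_v), 0)
  expect_equal(sum(pi_v), 1, tolerance = 1e-12)
  expect_lt(sum(abs(as.vector(pi_v %*% M) - pi_v)), 1e-10)
})

test_that("directed laplacian matches closed forms", {
  C <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  L <- directed_laplacian(dir_cycle3())$matrix
  expect_equal(L, diag(3) / 3 - (C + t(C)) / 6, tolerance = 1e-10)
  expect_equal(sort(eigen(L, only.values = TRUE)$values), c(0, 0.5, 0.5),
               tolerance = 1e-10)
  expect_equal(directed_laplacian(bidir_pair())$matrix,
               rbind(c(0.5, -0.5), c(-0.5, 0.5)), tolerance = 1e-10)
})

test_that("directed normalised laplacian matches closed forms and the conjugation identity", {
  C <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  Lt <- directed_normalised_laplacian(dir_cycle3())$matrix
  expect_equal(Lt, diag(3) - (C + t(C)) / 2, tolerance = 1e-10)
  expect_equal(sort(eigen(Lt, only.values = TRUE)$values), c(0, 1.5, 1.5),
               tolerance = 1e-10)
  expect_equal(directed_normalised_laplacian(bidir_pair())$matrix,
               rbind(c(1, -1), c(-1, 1)), tolerance = 1e-10)
  for (s in 1:3) {
    g <- strongly_connected_digraph(8, 0.25, seed = s)
    L <- directed_laplacian(g)$matrix
    Lt <- directed_normalised_laplacian(g)$matrix
    pis <- sqrt(stationary_distribution(transition_matrix(g)))
    expect_lt(max(abs(Lt - L / outer(pis, pis))), 1e-10)
    expect_lt(max(abs(rowSums(L))), 1e-12)
  }
})

test_that("all laplacian variants are PSD and annihilate their null vector", {
  g <- nonregular_er(9, 0.4, seed = 21)
  d <- strongly_connected_digraph(9, 0.3, seed = 22)
  checks <- list(
    list(laplacian(g)$matrix, rep(1, 9)),
    list(normalised_laplacian(g)$matrix, sqrt(degrees(g))),
    list(directed_laplacian(d)$matrix, rep(1, 9)),
    list(directed_normalised_laplacian(d)$matrix,
         sqrt(stationary_distribution(transition_matrix(d))))
  )
  for (ch in checks) {
    ev <- eigen(ch[[1]], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_lt(max(abs(ch[[1]] %*% ch[[2]])), 1e-8)
  }
  expect_lt(max(eigen(normalised_laplacian(g)$matrix,
                      only.values = TRUE)$values), 2 + 1e-10)
})

test_that("relabeling nodes conjugates every operator", {
  g <- nonregular_er(7, 0.5, seed = 31)
  p <- isomorphic_copy(g, seed = 32)
  h <- p$graph
  perm <- p$permutation
  for (op in list(laplacian, normalised_laplacian)) {
    expect_equal(op(h)$matrix, op(g)$matrix[perm, perm],
                 tolerance = 1e-12)
  }
  d <- strongly_connected_digraph(7, 0.3, seed = 33)
  pd <- isomorphic_copy(d, seed = 34)
  for (op in list(directed_laplacian, directed_normalised_laplacian)) {
    expect_equal(op(pd$graph)$matrix, op(d)$matrix[pd$permutation,
                                                   pd$permutation],
                 tolerance = 1e-9)
  }
})

test_that("symmetrize projects onto symmetric matrices and is idempotent", {
  arc <- graph_from_edges(2, 1, 2, directed = TRUE)
  s <- symmetrize(arc)
  expect_false(s$directed)
  expect_equal(s$adjacency, rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(symmetrize(bidir_pair())$adjacency, bidir_pair()$adjacency)
  d <- strongly_connected_digraph(6, 0.4, seed = 41)
  expect_equal(symmetrize(symmetrize(d)), symmetrize(d))
})

test_that("spectral decomposition reconstructs H and groups degeneracies", {
  sp <- spectral_decomposition(laplacian(k3()))
  expect_length(sp$groups, 2)
  expect_equal(sp$representatives, c(0, 3), tolerance = 1e-12)
  expect_equal(lengths(sp$groups), c(1L, 2L))
  expect_length(spectral_decomposition(diag(5))$groups, 1)
  sp3 <- spectral_decomposition(laplacian(path3()))
  expect_equal(sp3$representatives, c(0, 1, 3), tolerance = 1e-12)
  expect_equal(lengths(sp3$groups), rep(1L, 3))
  # orthonormality and reconstruction invariants
  H <- laplacian(nonregular_er(10, 0.4, seed = 51))$matrix
  sp <- spectral_decomposition(H)
  expect_lt(max(abs(crossprod(sp$vectors) - diag(10))), 1e-8)
  expect_lt(max(abs(sp$vectors %*% diag(sp$values) %*% t(sp$vectors) - H)),
            1e-8 * max(1, max(abs(H))))
  expect_error(spectral_decomposition(rbind(c(0, 1), c(0, 0))), "symmetric")
})
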