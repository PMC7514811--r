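test_that("isomorphic graphs attain kernel value 1 for every Hamiltonian", {
  g <- nonregular_er(8, 0.4, seed = 1)
  cp <- isomorphic_copy(g, seed = 2)$graph
  for (h in c("adjacency", "laplacian", "normalised_laplacian")) {
    expect_equal(kernel_pair(g, cp, kernel_options(h)), 1,
                 tolerance = 1e-6)
  }
  d <- strongly_connected_digraph(7, 0.3, seed = 3)
  dp <- isomorphic_copy(d, seed = 4)$graph
  for (h in c("directed_laplacian", "directed_normalised_laplacian")) {
    expect_equal(kernel_pair(d, dp, kernel_options(h)), 1,
                 tolerance = 1e-6)
  }
  # self-comparison through the pd closed form
  expect_equal(kernel_pd_pair(g, g), 1, tolerance = 1e-12)
})

test_that("kernel values are symmetric and bounded", {
  for (s in 1:5) {
    g1 <- er_graph(5 + s, 0.4, seed = 40 + s)
    g2 <- er_graph(4 + s, 0.5, seed = 50 + s)
    k12 <- kernel_pair(g1, g2)
    expect_equal(k12, kernel_pair(g2, g1), tolerance = 1e-10)
    expect_gte(k12, -1e-9)
    expect_lte(k12, 1 + 1e-9)
  }
})

test_that("finite-time kernels approach the infinite-time value", {
  g1 <- nonregular_er(6, 0.5, seed = 61)
  g2 <- nonregular_er(6, 0.4, seed = 62)
  kinf <- kernel_pair(g1, g2, kernel_options("laplacian", time = Inf))
  kT <- kernel_pair(g1, g2, kernel_options("laplacian", time = 1e4))
  expect_equal(kT, kinf, tolerance = 1e-2)
})

test_that("signature-weighted kernels keep the isomorphism property", {
  g <- nonregular_er(7, 0.45, seed = 71)
  cp <- isomorphic_copy(g, seed = 72)$graph
  for (sig in c("hks", "wks")) {
    k <- kernel_pair(g, cp, kernel_options("laplacian", signature = sig))
    expect_equal(k, 1, tolerance = 1e-6)
  }
})

test_that("the spectral distribution matches a hand-built eigendecomposition", {
  # path on 3 nodes: degrees (1,2,1), Laplacian eigenvalues {0,1,3}
  g <- path3()
  f <- graph_spectral_distribution(g)
  expect_equal(f$support, c(0, 1, 3) - 3, tolerance = 1e-10)
  # explicit oracle: centred degrees (-1/3, 2/3, -1/3) scaled to ||.||^2=1/2
  xi <- c(-1, 2, -1) / 3
  xi <- xi / sqrt(sum(xi^2)) / sqrt(2)
  eig <- eigen(rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               symmetric = TRUE)
  mass <- sapply(3:1, function(j) 2 * sum(crossprod(eig$vectors[, j], xi)^2))
  expect_equal(f$probs, mass, tolerance = 1e-10)
  expect_equal(sum(f$probs), 1, tolerance = 1e-12)
  # the eigenvector for lambda = 1 is odd around the centre while xi is
  # even, so all mass sits on the lambda = 3 eigenspace
  expect_equal(f$probs, c(0, 0, 1), tolerance = 1e-10)
  # zero mass always at the shifted zero eigenvalue
  g2 <- nonregular_er(7, 0.5, seed = 81)
  f2 <- graph_spectral_distribution(g2)
  expect_equal(f2$probs[which.min(abs(f2$support - (0 - 7)))], 0,
               tolerance = 1e-12)
  expect_equal(sum(f2$probs), 1, tolerance = 1e-10)
  # permutation invariance
  cp <- isomorphic_copy(g2, seed = 82)$graph
  fp <- graph_spectral_distribution(cp)
  expect_equal(fp$support, f2$support, tolerance = 1e-9)
  expect_equal(fp$probs, f2$probs, tolerance = 1e-9)
  expect_error(graph_spectral_distribution(k3()), "regular")
})

test_that("cjsd handles identical, disjoint, and near-coincident supports", {
  f <- new_energy_dist_for_test(c(-2, 1, 4), c(0.2, 0.5, 0.3))
  expect_equal(cjsd(f, f), 0, tolerance = 1e-12)
  g <- new_energy_dist_for_test(c(-5, 7), c(0.6, 0.4))
  expect_equal(cjsd(f, g), 1, tolerance = 1e-12)
  # brute-force pairing oracle on near-coincident supports: atoms within
  # tol collapse, atoms outside stay separate
  f1 <- new_energy_dist_for_test(c(0, 1), c(0.5, 0.5))
  f2 <- new_energy_dist_for_test(c(1 + 1e-12, 3), c(0.5, 0.5))
  mix_probs <- c(0.25, 0.5, 0.25)  # atoms {0}, {1,1+eps}, {3}
  expected <- -sum(mix_probs * log2(mix_probs)) - 1
  expect_equal(cjsd(f1, f2, support_tol = 1e-9), expected,
               tolerance = 1e-10)
  # with a tolerance below the separation the atoms stay apart
  expect_equal(cjsd(f1, f2, support_tol = 1e-14), 1, tolerance = 1e-10)
})

test_that("the closed form equals the density-matrix route", {
  # the central oracle: Theorem-scope kernel via per-graph spectra vs the
  # full merged-graph pinching with constrained initial states
  pairs <- list(
    list(path3(), star4()),
    list(nonregular_er(5, 0.5, seed = 91), nonregular_er(5, 0.4, seed = 92)),
    list(nonregular_er(7, 0.4, seed = 93), nonregular_er(4, 0.6, seed = 94)),
    list(nonregular_er(6, 0.5, seed = 95), nonregular_er(6, 0.5, seed = 96))
  )
  for (pr in pairs) {
    k_closed <- kernel_pd_pair(pr[[1]], pr[[2]])
    mg <- merge_graphs(pr[[1]], pr[[2]])
    st <- constrained_initial_states(mg)
    sp <- spectral_decomposition(laplacian(mg$graph))
    k_dm <- qjsd(infinite_time_density(st$psi_minus, sp),
                 infinite_time_density(st$psi_plus, sp))
    expect_equal(k_closed, k_dm, tolerance = 1e-8)
  }
})

test_that("the merged laplacian eigensystem has the predicted structure", {
  g1 <- nonregular_er(6, 0.5, seed = 101)
  g2 <- nonregular_er(4, 0.6, seed = 102)
  n <- 6; m <- 4
  L <- laplacian(merge_graphs(g1, g2)$graph)$matrix
  # smallest eigenvalue 0 with the constant eigenvector
  expect_lt(max(abs(L %*% rep(1, n + m))), 1e-8)
  # eigenvalue m+n with eigenvector (m 1_n, -n 1_m)
  v <- c(rep(m, n), rep(-n, m))
  expect_lt(max(abs(L %*% v - (m + n) * v)), 1e-8)
  # non-constant eigenvectors of L1 embed as (v, 0) with eigenvalue v+m
  e1 <- eigen(laplacian(g1)$matrix, symmetric = TRUE)
  for (j in 1:(n - 1)) {   # ascending order puts the constant vector last
    v1 <- e1$vectors[, j]
    if (abs(sum(v1)) > 1e-8) next
    emb <- c(v1, rep(0, m))
    expect_lt(max(abs(L %*% emb - (e1$values[j] + m) * emb)), 1e-8)
  }
})

test_that("pd-variant Gram matrices are positive semi-definite", {
  graphs <- lapply(1:12, function(s) nonregular_er(4 + s %% 5, 0.5,
                                                   seed = 110 + s))
  K <- gram_matrix(graphs, kernel_options(variant = "pd"))
  expect_equal(unclass(K), t(unclass(K)))
  expect_equal(diag(unclass(K)), setNames(rep(1, 12), rownames(K)),
               tolerance = 1e-8)
  mineig <- min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(mineig, -1e-8)
})

test_that("gram_matrix agrees with looped kernel_pair calls", {
  graphs <- list(nonregular_er(5, 0.5, seed = 121),
                 nonregular_er(6, 0.4, seed = 122),
                 nonregular_er(5, 0.5, seed = 121))  # duplicate
  K <- gram_matrix(graphs, kernel_options("laplacian"))
  for (i in 1:3) for (j in 1:3)
    expect_equal(K[i, j], kernel_pair(graphs[[i]], graphs[[j]]),
                 tolerance = 1e-10)
  # duplicated graph gives identical rows
  expect_equal(unname(K[1, ]), unname(K[3, ]), tolerance = 1e-12)
  K1 <- gram_matrix(graphs[1], kernel_options("laplacian"))
  expect_equal(dim(K1), c(1L, 1L))
  expect_equal(K1[1, 1], 1, tolerance = 1e-8)
  # failing pairs are recorded, not fatal
  withreg <- list(nonregular_er(5, 0.5, seed = 121), k3())
  expect_warning(Kf <- gram_matrix(withreg, kernel_options(variant = "pd")),
                 "failed")
  expect_true(anyNA(unclass(Kf)))
  expect_false(is.null(attr(Kf, "errors")))
})

test_that("kernel options enforce the pd-variant scope", {
  expect_error(kernel_options("adjacency", variant = "pd"), "Laplacian")
  expect_error(kernel_options("laplacian", time = 10, variant = "pd"),
               "infinite")
  expect_error(kernel_pair(random_directed_tree(4, 1),
                           random_directed_tree(4, 2),
                           kernel_options("laplacian")), "undirected")
})
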