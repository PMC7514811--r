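#' @section Hamiltonians:
#' A continuous-time quantum walk evolves under a symmetric (real
#' Hermitian) operator encoding the graph.  For undirected graphs the
#' package supports the adjacency matrix, the combinatorial Laplacian
#' `L = D - A`, and the symmetric normalised Laplacian
#' `D^{-1/2} L D^{-1/2}`.  For directed graphs it supports Chung's
#' directed Laplacian and its normalised form, built from the random-walk
#' transition matrix and its stationary distribution.
#' @name qwkernel-hamiltonians
NULL

new_hamiltonian <- function(matrix, kind, source_n = nrow(matrix)) {
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-10 * max(1, max(abs(matrix))))
    stop("Hamiltonian must be symmetric")
  matrix <- (matrix + t(matrix)) / 2  # clean floating-point asymmetry
  structure(list(matrix = matrix, kind = kind, source_n = source_n),
            class = "qw_hamiltonian")
}

#' @export
print.qw_hamiltonian <- function(x, ...) {
  cat(sprintf("<qw_hamiltonian> kind = %s, %d x %d\n", x$kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Graph Laplacian
#'
#' The combinatorial Laplacian `L = D - A` of an undirected graph, with
#' `D` the diagonal matrix of (weighted) degrees.  `L` is positive
#' semi-definite and annihilates the constant vector.
#'
#' @param g an undirected `qw_graph`.
#' @return a `qw_hamiltonian` of kind `"laplacian"`.
#' @export
laplacian <- function(g) {
  stop_not_graph(g)
  if (g$directed)
    stop("laplacian() requires an undirected graph; use directed_laplacian()")
  new_hamiltonian(diag(degrees(g), g$n_nodes) - g$adjacency, "laplacian")
}

#' Normalised graph Laplacian
#'
#' The symmetric normalised Laplacian `D^{-1/2} L D^{-1/2}` of an
#' undirected graph.  Isolated nodes use the convention
#' `D^{-1/2}[u, u] = 0`, leaving a zero row and column.  Eigenvalues lie
#' in `[0, 2]`.
#'
#' @param g an undirected `qw_graph`.
#' @return a `qw_hamiltonian` of kind `"normalised_laplacian"`.
#' @export
normalised_laplacian <- function(g) {
  stop_not_graph(g)
  if (g$directed)
    stop("normalised_laplacian() requires an undirected graph; ",
         "use directed_normalised_laplacian()")
  d <- degrees(g)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(d, g$n_nodes) - g$adjacency
  M <- L * outer(dinv, dinv)
  new_hamiltonian(M, "normalised_laplacian")
}

#' Random-walk transition matrix
#'
#' Row-stochastic transition matrix `M[u, v] = A[u, v] / d_out(u)` of the
#' classical random walk on a graph.  Rows of sink nodes (out-degree 0)
#' are all zero.
#'
#' @param g a `qw_graph` (undirected graphs use the ordinary degree).
#' @return an `n x n` numeric matrix.
#' @export
transition_matrix <- function(g) {
  stop_not_graph(g)
  dout <- rowSums(g$adjacency)
  M <- g$adjacency
  pos <- dout > 0
  M[pos, ] <- M[pos, , drop = FALSE] / dout[pos]
  M[!pos, ] <- 0
  M
}

#' Stationary distribution of a strongly connected chain
#'
#' The unique nonnegative left eigenvector `pi` of a row-stochastic
#' transition matrix with `pi M = pi` and `sum(pi) = 1`, computed by
#' power iteration on the lazy chain `(I + M) / 2`.  The lazy chain has
#' the same fixed point but is aperiodic, so the iteration converges even
#' on periodic graphs such as directed cycles.
#'
#' @param m row-stochastic transition matrix whose support is strongly
#'   connected.
#' @param max_iter maximum number of iterations (default `1e5`).
#' @param tol convergence tolerance on `||pi M - pi||_1`
#'   (default `1e-12`).
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(m, max_iter = 1e5, tol = 1e-12) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m)) stop("transition matrix must be square")
  memb <- igraph::components(
    igraph::graph_from_adjacency_matrix(m > 0, mode = "directed"),
    mode = "strong")$membership
  if (length(unique(memb)) > 1L)
    stop(sprintf(
      "chain is not strongly connected: %d strong components (sizes %s)",
      length(unique(memb)), paste(table(memb), collapse = ", ")))
  pi_v <- rep(1 / n, n)
  lazy <- (diag(n) + m) / 2
  for (i in seq_len(max_iter)) {
    nxt <- as.vector(pi_v %*% lazy)
    nxt <- nxt / sum(nxt)
    if (sum(abs(nxt - pi_v)) < tol / 2) {
      pi_v <- nxt
      res <- sum(abs(as.vector(pi_v %*% m) - pi_v))
      if (res < tol) return(pi_v)
    } else {
      pi_v <- nxt
    }
  }
  res <- sum(abs(as.vector(pi_v %*% m) - pi_v))
  stop(sprintf("stationary distribution did not converge in %d iterations (residual %.3e)",
               as.integer(max_iter), res))
}

#' Chung's Laplacian of a directed graph
#'
#' For a strongly connected directed graph with transition matrix `M` and
#' stationary distribution `pi` (diagonalised as `Pi`), the directed
#' Laplacian is the symmetric positive semi-definite matrix
#' `L = Pi - (Pi M + t(M) Pi) / 2`.  Its rows sum to zero.
#'
#' @param g a strongly connected directed `qw_graph` (undirected graphs,
#'   which are trivially strongly connected when connected, are accepted
#'   too).
#' @return a `qw_hamiltonian` of kind `"directed_laplacian"`.
#' @export
directed_laplacian <- function(g) {
  stop_not_graph(g)
  M <- transition_matrix(g)
  pi_v <- stationary_distribution(M)
  P <- diag(pi_v, g$n_nodes)
  L <- P - (P %*% M + t(M) %*% P) / 2
  new_hamiltonian(L, "directed_laplacian")
}

#' Chung's normalised Laplacian of a directed graph
#'
#' `I - (Pi^{1/2} M Pi^{-1/2} + Pi^{-1/2} t(M) Pi^{1/2}) / 2`, the
#' normalised companion of [directed_laplacian()].  It satisfies
#' `Ltilde = Pi^{-1/2} L Pi^{-1/2}` and has eigenvalues in `[0, 2]`.
#'
#' @inheritParams directed_laplacian
#' @return a `qw_hamiltonian` of kind `"directed_normalised_laplacian"`.
#' @export
directed_normalised_laplacian <- function(g) {
  stop_not_graph(g)
  M <- transition_matrix(g)
  pi_v <- stationary_distribution(M)
  s <- sqrt(pi_v)
  # Pi^{1/2} M Pi^{-1/2} has entries s_u M_uv / s_v
  S <- M * outer(s, 1 / s)
  L <- diag(g$n_nodes) - (S + t(S)) / 2
  new_hamiltonian(L, "directed_normalised_laplacian")
}

#' Build the Hamiltonian of a graph by name
#'
#' Dispatcher used by the kernel pipeline: `"adjacency"`, `"laplacian"`
#' and `"normalised_laplacian"` for undirected graphs,
#' `"directed_laplacian"` and `"directed_normalised_laplacian"` for
#' directed ones.
#'
#' @param g a `qw_graph`.
#' @param kind Hamiltonian name (see Details).
#' @return a `qw_hamiltonian`.
#' @export
graph_hamiltonian <- function(g, kind = c("laplacian", "adjacency",
                                          "normalised_laplacian",
                                          "directed_laplacian",
                                          "directed_normalised_laplacian")) {
  stop_not_graph(g)
  kind <- match.arg(kind)
  undirected_kinds <- c("adjacency", "laplacian", "normalised_laplacian")
  if (g$directed && kind %in% undirected_kinds)
    stop(sprintf("Hamiltonian kind '%s' requires an undirected graph", kind))
  if (!g$directed && !(kind %in% undirected_kinds))
    stop(sprintf("Hamiltonian kind '%s' requires a directed graph", kind))
  switch(kind,
    adjacency = new_hamiltonian(g$adjacency, "adjacency"),
    laplacian = laplacian(g),
    normalised_laplacian = normalised_laplacian(g),
    directed_laplacian = directed_laplacian(g),
    directed_normalised_laplacian = directed_normalised_laplacian(g)
  )
}

#' Spectral decomposition with degeneracy grouping
#'
#' Eigendecomposition `H = Phi Lambda t(Phi)` of a symmetric Hamiltonian
#' with eigenvalues in ascending order, plus a partition of the indices
#' into clusters of (numerically) degenerate eigenvalues.  Clusters are
#' formed by single-linkage on the sorted eigenvalues: consecutive
#' eigenvalues closer than `degeneracy_tol` belong to the same cluster.
#' The clusters determine the eigenprojectors used by the infinite-time
#' average of the walk.
#'
#' @param h a `qw_hamiltonian` or symmetric numeric matrix.
#' @param degeneracy_tol gap threshold; default
#'   `1e-9 * max(1, spectral radius)`.
#' @return an object of class `qw_spectrum` with fields `values`
#'   (ascending), `vectors` (orthonormal columns), `groups` (list of
#'   index vectors), `representatives` (one value per group) and
#'   `degeneracy_tol`.
#' @export
spectral_decomposition <- function(h, degeneracy_tol = NULL) {
  M <- if (inherits(h, "qw_hamiltonian")) h$matrix else as.matrix(h)
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M))))
    stop("spectral_decomposition() requires a symmetric matrix")
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  n <- length(values)
  if (is.null(degeneracy_tol))
    degeneracy_tol <- 1e-9 * max(1, max(abs(values)))
  grp <- integer(n)
  grp[1] <- 1L
  if (n > 1) for (i in 2:n)
    grp[i] <- if (values[i] - values[i - 1] <= degeneracy_tol)
      grp[i - 1] else grp[i - 1] + 1L
  groups <- split(seq_len(n), grp)
  names(groups) <- NULL
  representatives <- vapply(groups, function(ix) mean(values[ix]), numeric(1))
  structure(
    list(values = values, vectors = vectors, groups = groups,
         representatives = representatives, degeneracy_tol = degeneracy_tol),
    class = "qw_spectrum"
  )
}

#' @export
print.qw_spectrum <- function(x, ...) {
  cat(sprintf("<qw_spectrum> %d eigenvalues in %d degenerate clusters\n",
              length(x$values), length(x$groups)))
  invisible(x)
}
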