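#' Erdos-Renyi random graph
#'
#' Each (ordered, for directed graphs) node pair carries an edge
#' independently with probability `p`.  With
#' `require_connected = TRUE` the draw is repeated (up to `max_tries`
#' times) until the graph is connected (strongly connected when
#' directed).  All generators in the package are pure functions of
#' their arguments including `seed` and leave the caller's RNG state
#' untouched.
#'
#' @param n number of nodes.
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @param directed logical.
#' @param require_connected resample until (strongly) connected.
#' @param max_tries retry budget for `require_connected`.
#' @return a `qw_graph`.
#' @export
er_graph <- function(n, p, seed, directed = FALSE,
                     require_connected = FALSE, max_tries = 100) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      A <- matrix(0, n, n)
      if (directed) {
        off <- which(row(A) != col(A))
        A[off] <- as.numeric(stats::runif(length(off)) < p)
      } else {
        ut <- which(upper.tri(A))
        A[ut] <- as.numeric(stats::runif(length(ut)) < p)
        A <- A + t(A)
      }
      g <- graph_from_adjacency(A, directed = directed)
      if (!require_connected || is_connected_graph(g)) return(g)
    }
    stop(sprintf("no connected draw in %d tries (n = %d, p = %g)",
                 max_tries, n, p))
  })
}

#' Isomorphic copy of a graph
#'
#' Conjugates the adjacency matrix by a seeded random node permutation.
#' The returned permutation `p` certifies the isomorphism:
#' `copy$adjacency[i, j] == g$adjacency[p[i], p[j]]`.
#'
#' @param g a `qw_graph`.
#' @param seed integer seed.
#' @return list with `graph` (the permuted copy) and `permutation`.
#' @export
isomorphic_copy <- function(g, seed) {
  stop_not_graph(g)
  p <- with_seed(seed, sample.int(g$n_nodes))
  A <- g$adjacency[p, p, drop = FALSE]
  list(graph = graph_from_adjacency(A, directed = g$directed,
                                    node_ids = g$node_ids[p]),
       permutation = p)
}

#' Random directed tree
#'
#' A rooted tree on `n` nodes with all arcs oriented from the root
#' toward the leaves: node `i > 1` receives an arc from a uniformly
#' chosen earlier node.  Node 1 is the root.
#'
#' @param n number of nodes (at least 1).
#' @param seed integer seed.
#' @return a directed `qw_graph` with `n - 1` arcs.
#' @export
random_directed_tree <- function(n, seed) {
  if (n < 1) stop("n must be at least 1")
  A <- matrix(0, n, n)
  if (n > 1) {
    parents <- with_seed(seed,
      vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
    for (i in 2:n) A[parents[i - 1], i] <- 1
  }
  graph_from_adjacency(A, directed = TRUE)
}

#' Random strongly connected digraph
#'
#' A Hamiltonian cycle through a seeded random node order guarantees
#' strong connectivity; every remaining ordered pair receives an extra
#' arc independently with probability `extra_edge_prob`.
#'
#' @param n number of nodes (at least 2).
#' @param extra_edge_prob probability of each extra arc.
#' @param seed integer seed.
#' @return a strongly connected directed `qw_graph`.
#' @export
strongly_connected_digraph <- function(n, extra_edge_prob = 0.2, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  with_seed(seed, {
    ord <- sample.int(n)
    A <- matrix(0, n, n)
    for (i in seq_len(n))
      A[ord[i], ord[if (i == n) 1 else i + 1]] <- 1
    off <- which(row(A) != col(A) & A == 0)
    A[off] <- as.numeric(stats::runif(length(off)) < extra_edge_prob)
    graph_from_adjacency(A, directed = TRUE)
  })
}

#' Planted two-class graph dataset
#'
#' Deterministic generator of a labelled graph sample with a known
#' class signal, used to exercise the classification harness without
#' external data.
#'
#' Undirected mode: class 1 graphs are Erdos-Renyi with density `p_a`,
#' class 2 with density `p_b`; the signal lives in the edge density.
#'
#' Directed mode encodes the class purely in arc orientations: the two
#' classes share the same undirected skeletons (graph `i` of class 1
#' and graph `i` of class 2 are built on an identical
#' Erdos-Renyi skeleton of density `p_a`).  Class 1 orients every
#' skeleton edge along a seeded random topological order (a
#' feed-forward, acyclic flow); class 2 orients each edge independently
#' at random.  Symmetrizing the graphs therefore destroys the class
#' signal exactly — the symmetrized copies of a pair are identical
#' matrices with opposite labels — while directed-Laplacian kernels can
#' still see it.
#'
#' @param n_per_class graphs per class.
#' @param n_nodes nodes per graph.
#' @param seed integer seed.
#' @param directed logical; selects the mode described above.
#' @param p_a edge density of class 1 (and of the shared skeletons in
#'   directed mode).
#' @param p_b edge density of class 2 (undirected mode only).
#' @return an object of class `qw_dataset`: list with `graphs`,
#'   `labels` (integer 1/2) and `name`.
#' @export
planted_two_class <- function(n_per_class, n_nodes, seed,
                              directed = FALSE, p_a = 0.3, p_b = 0.45) {
  graphs <- vector("list", 2 * n_per_class)
  labels <- rep(1:2, each = n_per_class)
  if (!directed) {
    for (i in seq_len(n_per_class)) {
      graphs[[i]] <- er_graph(n_nodes, p_a, seed = seed + i)
      graphs[[n_per_class + i]] <-
        er_graph(n_nodes, p_b, seed = seed + 100000 + i)
    }
  } else {
    for (i in seq_len(n_per_class)) {
      skel <- er_graph(n_nodes, p_a, seed = seed + i,
                       require_connected = TRUE)
      built <- with_seed(seed + 200000 + i, {
        ord <- sample.int(n_nodes)      # topological order for class 1
        rank <- order(ord)
        ut <- which(upper.tri(skel$adjacency) & skel$adjacency > 0,
                    arr.ind = TRUE)
        A_ff <- matrix(0, n_nodes, n_nodes)
        A_rnd <- matrix(0, n_nodes, n_nodes)
        flips <- stats::runif(nrow(ut)) < 0.5
        for (e in seq_len(nrow(ut))) {
          u <- ut[e, 1]; v <- ut[e, 2]
          if (rank[u] < rank[v]) A_ff[u, v] <- 1 else A_ff[v, u] <- 1
          if (flips[e]) A_rnd[u, v] <- 1 else A_rnd[v, u] <- 1
        }
        list(ff = A_ff, rnd = A_rnd)
      })
      graphs[[i]] <- graph_from_adjacency(built$ff, directed = TRUE)
      graphs[[n_per_class + i]] <-
        graph_from_adjacency(built$rnd, directed = TRUE)
    }
  }
  structure(list(graphs = graphs, labels = labels,
                 name = sprintf("planted_%s_%dx%d",
                                if (directed) "directed" else "undirected",
                                2 * n_per_class, n_nodes)),
            class = "qw_dataset")
}

#' @export
print.qw_dataset <- function(x, ...) {
  cat(sprintf("<qw_dataset> %s: %d graphs, %d classes\n", x$name,
              length(x$graphs), length(unique(x$labels))))
  invisible(x)
}
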