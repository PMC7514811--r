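#' Construct a graph from an adjacency matrix
#'
#' The basic container used throughout the package: a (possibly weighted)
#' graph stored as a dense nonnegative adjacency matrix with a zero
#' diagonal.  Undirected graphs must have an exactly symmetric adjacency
#' matrix; directed graphs may not.
#'
#' @param adjacency square numeric matrix with nonnegative entries and a
#'   zero diagonal.  Entry `(u, v)` is the weight of the edge from `u`
#'   to `v` (1 for unweighted graphs).
#' @param directed logical; if `NULL` (default), inferred from the
#'   symmetry of `adjacency`.
#' @param node_ids optional character vector of stable node labels;
#'   defaults to `"v1" ... "vn"`.
#' @return an object of class `qw_graph` with fields `n_nodes`,
#'   `directed`, `adjacency` and `node_ids`.
#' @examples
#' g <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' degrees(g)
#' @export
graph_from_adjacency <- function(adjacency, directed = NULL, node_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency matrix must be square")
  if (!is.numeric(adjacency) || anyNA(adjacency))
    stop("adjacency matrix must be numeric with no missing values")
  if (any(adjacency < 0))
    stop("adjacency entries must be nonnegative")
  if (any(diag(adjacency) != 0))
    stop("self-loops are not supported: the diagonal must be zero")
  n <- nrow(adjacency)
  sym <- isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0,
                          check.attributes = FALSE))
  if (is.null(directed)) directed <- !sym
  if (!directed && !sym)
    stop("undirected graph requires an exactly symmetric adjacency matrix")
  if (is.null(node_ids))
    node_ids <- paste0("v", seq_len(n), recycle0 = TRUE)
  if (length(node_ids) != n) stop("node_ids length must equal node count")
  dimnames(adjacency) <- NULL
  structure(
    list(n_nodes = n, directed = directed, adjacency = adjacency,
         node_ids = as.character(node_ids)),
    class = "qw_graph"
  )
}

#' Construct a graph from an edge list
#'
#' @param n_nodes number of nodes.
#' @param from,to integer vectors of 1-based endpoint indices.
#' @param weight optional numeric vector of positive edge weights
#'   (default 1).
#' @param directed logical.  Undirected edges are stored symmetrically.
#' @param node_ids optional node labels.
#' @return a [graph_from_adjacency()] object.
#' @export
graph_from_edges <- function(n_nodes, from, to, weight = NULL,
                             directed = FALSE, node_ids = NULL) {
  if (length(from) != length(to)) stop("from and to must have equal length")
  if (is.null(weight)) weight <- rep(1, length(from))
  if (length(weight) == 1L) weight <- rep(weight, length(from))
  if (length(weight) != length(from)) stop("weight length mismatch")
  if (any(from < 1 | from > n_nodes | to < 1 | to > n_nodes))
    stop("edge endpoints out of range")
  if (any(from == to)) stop("self-loops are not supported")
  A <- matrix(0, n_nodes, n_nodes)
  for (i in seq_along(from)) {
    A[from[i], to[i]] <- weight[i]
    if (!directed) A[to[i], from[i]] <- weight[i]
  }
  graph_from_adjacency(A, directed = directed, node_ids = node_ids)
}

is_qw_graph <- function(x) inherits(x, "qw_graph")

stop_not_graph <- function(x) {
  if (!is_qw_graph(x)) stop("expected a qw_graph object")
  invisible(x)
}

#' @export
print.qw_graph <- function(x, ...) {
  n_edges <- if (x$directed) sum(x$adjacency > 0) else sum(x$adjacency > 0) / 2
  cat(sprintf("<qw_graph> %s, %d nodes, %g edges%s\n",
              if (x$directed) "directed" else "undirected",
              x$n_nodes, n_edges,
              if (all(x$adjacency %in% c(0, 1))) "" else " (weighted)"))
  invisible(x)
}

#' Node degrees
#'
#' Weighted degrees of a graph.  For undirected graphs the degree of `u`
#' is the row sum of the adjacency matrix.  For directed graphs the
#' out-degree is the row sum, the in-degree the column sum, and the
#' total degree their sum.
#'
#' @param g a `qw_graph`.
#' @param mode one of `"auto"` (default: total degree for undirected
#'   graphs, out-degree for directed ones), `"total_undirected"`,
#'   `"in"`, `"out"`, `"total_directed"`.
#' @return numeric vector of length `n_nodes`.
#' @export
degrees <- function(g, mode = c("auto", "total_undirected", "in", "out",
                                "total_directed")) {
  stop_not_graph(g)
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (g$directed) "out" else "total_undirected"
  switch(mode,
    total_undirected = rowSums(g$adjacency),
    out = rowSums(g$adjacency),
    "in" = colSums(g$adjacency),
    total_directed = rowSums(g$adjacency) + colSums(g$adjacency)
  )
}

#' Symmetrize a directed graph
#'
#' Projects the adjacency matrix onto the space of symmetric matrices,
#' `(A + t(A)) / 2`, yielding the undirected counterpart of a directed
#' graph.  Weights are retained, not re-binarized, so a unidirectional
#' unit edge becomes an undirected edge of weight 1/2.
#'
#' @param g a `qw_graph` (directed; undirected input is returned as is).
#' @return an undirected `qw_graph`.
#' @export
symmetrize <- function(g) {
  stop_not_graph(g)
  A <- (g$adjacency + t(g$adjacency)) / 2
  graph_from_adjacency(A, directed = FALSE, node_ids = g$node_ids)
}

as_igraph <- function(g) {
  mode <- if (g$directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = mode,
                                      weighted = TRUE, diag = FALSE)
}

#' Connectivity of a graph
#'
#' @param g a `qw_graph`.
#' @param mode `"strong"` (default for directed graphs) or `"weak"`;
#'   ignored for undirected graphs.
#' @return logical.
#' @export
is_connected_graph <- function(g, mode = c("strong", "weak")) {
  stop_not_graph(g)
  mode <- match.arg(mode)
  igraph::is_connected(as_igraph(g), mode = if (g$directed) mode else "weak")
}

strong_components <- function(g) {
  igraph::components(as_igraph(g), mode = "strong")$membership
}
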