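#' Merge two graphs with complete cross-connections
#'
#' Builds the arena on which both quantum walks evolve: the disjoint
#' union of `g1` (nodes `V1`) and `g2` (nodes `V2`) plus an undirected
#' edge between every `u` in `V1` and every `v` in `V2`.  The cross
#' edges are bidirectional even when the inputs are directed, so a
#' merged graph with both sides nonempty is always strongly connected.
#'
#' @param g1,g2 nonempty `qw_graph` objects with the same directedness.
#' @return an object of class `qw_merged` with fields `graph` (the
#'   merged `qw_graph`), `split` (index ranges of the two sides) and
#'   `weighted = FALSE`.
#' @examples
#' mg <- merge_graphs(er_graph(4, 0.5, seed = 1), er_graph(3, 0.5, seed = 2))
#' mg$graph
#' @export
merge_graphs <- function(g1, g2) {
  stop_not_graph(g1); stop_not_graph(g2)
  if (g1$n_nodes == 0 || g2$n_nodes == 0)
    stop("both graphs must be nonempty")
  if (g1$directed != g2$directed)
    stop("cannot merge a directed with an undirected graph")
  n <- g1$n_nodes; m <- g2$n_nodes
  A <- matrix(1, n + m, n + m)
  A[seq_len(n), seq_len(n)] <- g1$adjacency
  A[n + seq_len(m), n + seq_len(m)] <- g2$adjacency
  diag(A) <- 0
  ids <- c(paste0("g1.", g1$node_ids), paste0("g2.", g2$node_ids))
  g <- graph_from_adjacency(A, directed = g1$directed, node_ids = ids)
  structure(
    list(graph = g,
         split = list(v1 = seq_len(n), v2 = n + seq_len(m)),
         weighted = FALSE),
    class = "qw_merged"
  )
}

#' Merge two graphs with signature-derived edge weights
#'
#' Signature-weighted variant of [merge_graphs()]: every pair of distinct
#' nodes in the union (within either side as well as across) is
#' connected by an edge weighted by the similarity of the two nodes'
#' spectral signatures, turning the merged graph into a complete
#' weighted graph.  The original edge structure enters only through the
#' signatures, which are computed on the original graphs.
#'
#' Two weight modes are available.  `"similarity"` (default) maps the
#' Euclidean signature distance `omega` through a self-tuned Gaussian,
#' `w = exp(-omega^2 / (2 s^2))` with `s` the median pairwise distance,
#' so that similar signatures give heavy edges.  `"raw_distance"` uses
#' `omega` itself as the weight.
#'
#' @param g1,g2 nonempty undirected `qw_graph` objects.
#' @param s1,s2 `qw_signature` objects for `g1` and `g2` with matching
#'   kind and dimension.
#' @param weight_mode `"similarity"` or `"raw_distance"`.
#' @return a `qw_merged` with `weighted = TRUE`.
#' @export
merge_graphs_weighted <- function(g1, g2, s1, s2,
                                  weight_mode = c("similarity",
                                                  "raw_distance")) {
  stop_not_graph(g1); stop_not_graph(g2)
  weight_mode <- match.arg(weight_mode)
  if (g1$directed || g2$directed)
    stop("signature-weighted merging requires undirected graphs")
  if (g1$n_nodes == 0 || g2$n_nodes == 0)
    stop("both graphs must be nonempty")
  if (!inherits(s1, "qw_signature") || !inherits(s2, "qw_signature"))
    stop("s1 and s2 must be qw_signature objects")
  if (s1$kind != s2$kind)
    stop("signature kinds differ: ", s1$kind, " vs ", s2$kind)
  if (ncol(s1$values) != ncol(s2$values))
    stop("signature dimensions differ")
  if (nrow(s1$values) != g1$n_nodes || nrow(s2$values) != g2$n_nodes)
    stop("signature row counts must match the graphs")
  FF <- rbind(s1$values, s2$values)
  sq <- rowSums(FF^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(FF), 0)
  omega <- sqrt(D2)
  diag(omega) <- 0
  if (weight_mode == "similarity") {
    off <- omega[upper.tri(omega)]
    s <- stats::median(off)
    if (s <= 0) {
      warning("all pairwise signature distances are (near) zero; ",
              "similarity weights degenerate to 1")
      s <- 1
    }
    W <- exp(-omega^2 / (2 * s^2))
  } else {
    W <- omega
    if (all(W[upper.tri(W)] == 0))
      warning("all raw signature distances are zero: the merged graph ",
              "has no edges")
  }
  diag(W) <- 0
  n <- g1$n_nodes
  ids <- c(paste0("g1.", g1$node_ids), paste0("g2.", g2$node_ids))
  g <- graph_from_adjacency(W, directed = FALSE, node_ids = ids)
  structure(
    list(graph = g,
         split = list(v1 = seq_len(n), v2 = n + seq_len(g2$n_nodes)),
         weighted = TRUE),
    class = "qw_merged"
  )
}

#' @export
print.qw_merged <- function(x, ...) {
  cat(sprintf("<qw_merged> %d + %d nodes%s\n", length(x$split$v1),
              length(x$split$v2), if (x$weighted) " (signature-weighted)" else ""))
  invisible(x)
}

new_state_pair <- function(psi_minus, psi_plus, convention) {
  structure(list(psi_minus = psi_minus, psi_plus = psi_plus,
                 convention = convention),
            class = "qw_state_pair")
}

#' @export
print.qw_state_pair <- function(x, ...) {
  cat(sprintf("<qw_state_pair> convention = %s, dimension %d\n",
              x$convention, length(x$psi_plus)))
  invisible(x)
}

#' Interference-engineered initial states on a merged graph
#'
#' The constructive state `psi_plus` has amplitudes proportional to the
#' node degrees with equal phase everywhere; the destructive state
#' `psi_minus` flips the sign on the second side.  Directed merged
#' graphs use out-degrees.  Both states are normalised to unit length.
#'
#' By default the degrees are read from the merged graph — the structure
#' the walk actually evolves on, where every node additionally gains the
#' complete set of cross edges.  `degree_source = "original"` restricts
#' the degree computation to each side's internal block instead.
#'
#' @param mg a `qw_merged`.
#' @param degree_source `"merged"` (default) or `"original"`.
#' @return a `qw_state_pair` with unit-norm numeric amplitude vectors.
#' @export
initial_states <- function(mg, degree_source = c("merged", "original")) {
  if (!inherits(mg, "qw_merged")) stop("expected a qw_merged object")
  degree_source <- match.arg(degree_source)
  A <- mg$graph$adjacency
  v1 <- mg$split$v1; v2 <- mg$split$v2
  if (degree_source == "merged") {
    d <- rowSums(A)  # out-degrees when directed, degrees otherwise
  } else {
    d <- numeric(nrow(A))
    d[v1] <- rowSums(A[v1, v1, drop = FALSE])
    d[v2] <- rowSums(A[v2, v2, drop = FALSE])
  }
  if (all(d[v1] == 0) || all(d[v2] == 0))
    stop("degree vector is identically zero on one side; ",
         "initial states are undefined")
  C <- sqrt(sum(d^2))
  psi_plus <- d / C
  psi_minus <- d / C
  psi_minus[v2] <- -psi_minus[v2]
  new_state_pair(psi_minus, psi_plus,
                 if (mg$graph$directed) "out_degree" else "degree")
}

#' Constrained initial states for the positive-definite kernel
#'
#' The variant of [initial_states()] whose restrictions `xi0` (side 1)
#' and `chi0` (side 2) are mean-centred and carry squared norm 1/2 each:
#' `<1|xi0> = <1|chi0> = 0` and `||xi0||^2 = ||chi0||^2 = 1/2`.  These
#' are the conditions under which the infinite-time kernel is provably
#' positive definite.  Centering flips the sign of the smallest degree
#' components, which perturbs the pure constructive/destructive phase
#' pattern of the unconstrained states.
#'
#' A side whose (merged) degree vector is constant — a regular side graph
#' — centres to zero and has no constrained state.  With
#' `perturb = TRUE` a deterministic perturbation (`1e-6` added to the
#' first node's degree before centering) is applied instead of raising
#' an error.
#'
#' @param mg a `qw_merged`.
#' @param perturb logical; apply the deterministic fallback for regular
#'   sides instead of failing.
#' @return a `qw_state_pair` with `convention = "constrained"`.
#' @export
constrained_initial_states <- function(mg, perturb = FALSE) {
  if (!inherits(mg, "qw_merged")) stop("expected a qw_merged object")
  A <- mg$graph$adjacency
  v1 <- mg$split$v1; v2 <- mg$split$v2
  side_state <- function(idx, side) {
    d <- rowSums(A[idx, , drop = FALSE])
    x <- d - mean(d)
    if (sqrt(sum(x^2)) < 1e-12 * max(1, max(abs(d)))) {
      if (!perturb)
        stop(sprintf(
          "side %d has a constant degree vector (regular graph): %s",
          side,
          "constrained states are unconstructible; see perturb = TRUE"))
      d[1] <- d[1] + 1e-6
      x <- d - mean(d)
    }
    x <- x / sqrt(sum(x^2))
    x <- x - mean(x)          # second pass absorbs rounding from the scaling
    x / sqrt(sum(x^2)) / sqrt(2)  # squared norm 1/2
  }
  xi0 <- side_state(v1, 1L)
  chi0 <- side_state(v2, 2L)
  psi_plus <- c(xi0, chi0)
  psi_minus <- c(xi0, -chi0)
  new_state_pair(psi_minus, psi_plus, "constrained")
}
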