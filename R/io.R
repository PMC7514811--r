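#' Read and write graphs as edge lists
#'
#' Plain-text exchange format: a one-line header `n_nodes directed`
#' (`directed` as 0/1), followed by one row per edge,
#' `u v [weight]`, with 0-based node indices.  Undirected edges are
#' listed once.
#'
#' @param g a `qw_graph`.
#' @param path file path.
#' @return `read_edge_list()` returns a `qw_graph`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
write_edge_list <- function(g, path) {
  stop_not_graph(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", g$n_nodes, as.integer(g$directed)), con)
  A <- g$adjacency
  idx <- if (g$directed) which(A > 0, arr.ind = TRUE) else {
    w <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
    w
  }
  if (nrow(idx) > 0) {
    wts <- A[idx]
    lines <- if (all(wts == 1))
      sprintf("%d %d", idx[, 1] - 1L, idx[, 2] - 1L)
    else
      sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L, wts)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2) stop("edge list header must be 'n_nodes directed'")
  n <- as.integer(hdr[1]); directed <- hdr[2] != 0
  A <- matrix(0, n, n)
  if (length(lines) > 1) {
    for (ln in lines[-1]) {
      f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(f) < 2 || length(f) > 3) stop("malformed edge row: ", ln)
      u <- f[1] + 1L; v <- f[2] + 1L
      w <- if (length(f) == 3) f[3] else 1
      A[u, v] <- w
      if (!directed) A[v, u] <- w
    }
  }
  graph_from_adjacency(A, directed = directed)
}

#' Read and write graphs in GraphML
#'
#' Thin wrappers over igraph's GraphML support, preserving node count
#' (including isolated nodes), directedness and the `weight` edge
#' attribute.
#'
#' @param g a `qw_graph`.
#' @param path file path.
#' @return `read_graphml()` returns a `qw_graph`; `write_graphml()`
#'   returns `path` invisibly.
#' @export
write_graphml <- function(g, path) {
  stop_not_graph(g)
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  attr <- if ("weight" %in% igraph::edge_attr_names(ig)) "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(ig, attr = attr, sparse = FALSE))
  graph_from_adjacency(A, directed = igraph::is_directed(ig))
}

#' Read a benchmark dataset in the adjacency-pair layout
#'
#' Loader for the layout used by the common graph-kernel benchmark
#' collections: `<name>_A.txt` (comma-separated node-pair rows, global
#' 1-based node ids), `<name>_graph_indicator.txt` (graph id of each
#' node) and `<name>_graph_labels.txt` (class label per graph).
#' Optional external datasets only; nothing in the package requires
#' them.
#'
#' @param dir directory containing the files.
#' @param name dataset prefix.
#' @param directed logical; the layout lists both arc directions for
#'   undirected graphs.
#' @return a `qw_dataset`.
#' @export
read_benchmark_dataset <- function(dir, name, directed = FALSE) {
  fp <- function(suffix) file.path(dir, paste0(name, suffix))
  A_rows <- utils::read.csv(fp("_A.txt"), header = FALSE,
                            strip.white = TRUE)
  indicator <- scan(fp("_graph_indicator.txt"), what = integer(),
                    quiet = TRUE)
  glabels <- scan(fp("_graph_labels.txt"), what = integer(), quiet = TRUE)
  n_graphs <- length(glabels)
  node_of_graph <- split(seq_along(indicator), indicator)
  graphs <- vector("list", n_graphs)
  for (gi in seq_len(n_graphs)) {
    nodes <- node_of_graph[[as.character(gi)]]
    local_id <- integer(max(nodes))
    local_id[nodes] <- seq_along(nodes)
    rows <- A_rows[A_rows[, 1] %in% nodes, , drop = FALSE]
    A <- matrix(0, length(nodes), length(nodes))
    if (nrow(rows) > 0)
      A[cbind(local_id[rows[, 1]], local_id[rows[, 2]])] <- 1
    if (!directed) A <- pmax(A, t(A))
    graphs[[gi]] <- graph_from_adjacency(A, directed = directed)
  }
  structure(list(graphs = graphs, labels = glabels, name = name),
            class = "qw_dataset")
}

#' Read and write dataset directories
#'
#' A dataset directory holds one edge-list file per graph
#' (`graph_0001.txt`, ...) plus a `labels.csv` table with columns
#' `graph` (file name) and `label`.
#'
#' @param ds a `qw_dataset`.
#' @param dir directory path (created if missing).
#' @return `read_dataset_dir()` returns a `qw_dataset`;
#'   `write_dataset_dir()` returns `dir` invisibly.
#' @export
write_dataset_dir <- function(ds, dir) {
  if (!inherits(ds, "qw_dataset")) stop("expected a qw_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("graph_%04d.txt", seq_along(ds$graphs))
  for (i in seq_along(ds$graphs))
    write_edge_list(ds$graphs[[i]], file.path(dir, files[i]))
  utils::write.csv(data.frame(graph = files, label = ds$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset_dir
#' @export
read_dataset_dir <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  graphs <- lapply(tab$graph, function(f) read_edge_list(file.path(dir, f)))
  structure(list(graphs = graphs, labels = tab$label,
                 name = basename(normalizePath(dir))),
            class = "qw_dataset")
}
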