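#' Heat kernel signature
#'
#' Per-node spectral descriptor built from the Laplacian eigenpairs:
#' `HKS(u, t) = sum_k exp(-lambda_k * t) * phi_k(u)^2`, the amount of
#' heat remaining at node `u` after time `t` when a unit of heat is
#' placed there at `t = 0`.  Columns conserve the heat trace:
#' `colSums(values)` equals `sum_k exp(-lambda_k * t)`.
#'
#' The default time grid follows the convention of the original
#' signature literature: 10 values log-spaced over
#' `[4 log(10) / lambda_max, 4 log(10) / lambda_min_pos]`, where
#' `lambda_min_pos` is the smallest positive Laplacian eigenvalue.
#'
#' @param g an undirected `qw_graph`.
#' @param times positive time samples; `NULL` for the default grid
#'   (requires at least one edge).
#' @param n_times number of samples in the default grid.
#' @return an object of class `qw_signature` with fields `values`
#'   (`n x k` matrix), `kind = "hks"` and `params`.
#' @export
heat_kernel_signature <- function(g, times = NULL, n_times = 10) {
  stop_not_graph(g)
  if (g$directed) stop("heat_kernel_signature() requires an undirected graph")
  spec <- spectral_decomposition(laplacian(g))
  if (is.null(times)) {
    pos <- spec$values[spec$values > 1e-12]
    if (length(pos) == 0)
      stop("default time grid needs a positive Laplacian eigenvalue; ",
           "supply times explicitly for an empty graph")
    t_min <- 4 * log(10) / max(pos)
    t_max <- 4 * log(10) / min(pos)
    times <- exp(seq(log(t_min), log(t_max), length.out = n_times))
  }
  if (length(times) == 0 || any(times < 0))
    stop("times must be a nonempty vector of nonnegative reals")
  Phi2 <- spec$vectors^2
  vals <- sapply(times, function(t) Phi2 %*% exp(-spec$values * t))
  vals <- matrix(vals, nrow = g$n_nodes)
  structure(
    list(values = vals, kind = "hks",
         params = list(times = times)),
    class = "qw_signature"
  )
}

#' Wave kernel signature
#'
#' Per-node descriptor of the average probability that a quantum wave
#' packet of a given energy is measured at each node:
#' `WKS(u, e) = C_e * sum_{k: lambda_k > 0} phi_k(u)^2 *
#' exp(-(e - log lambda_k)^2 / (2 sigma^2))`, where the energy grid `e`
#' spans `[log lambda_min_pos, log lambda_max]` and `C_e` normalises the
#' total energy response at each `e`.
#'
#' @param g a nonempty undirected `qw_graph` with at least one edge.
#' @param n_energies number of energy samples (at least 2).
#' @param sigma_scale bandwidth as a multiple of the energy grid
#'   spacing.
#' @return a `qw_signature` with `kind = "wks"`.
#' @export
wave_kernel_signature <- function(g, n_energies = 10, sigma_scale = 1) {
  stop_not_graph(g)
  if (g$directed) stop("wave_kernel_signature() requires an undirected graph")
  if (g$n_nodes == 0) stop("graph is empty")
  if (n_energies < 2) stop("n_energies must be at least 2")
  spec <- spectral_decomposition(laplacian(g))
  pos <- spec$values > 1e-12
  if (!any(pos))
    stop("wave kernel signature needs a positive Laplacian eigenvalue ",
         "(the graph has no edges)")
  loglam <- log(spec$values[pos])
  e_grid <- seq(min(loglam), max(loglam), length.out = n_energies)
  spacing <- if (n_energies > 1) e_grid[2] - e_grid[1] else 0
  sigma <- max(sigma_scale * spacing, 1e-8)
  Phi2 <- spec$vectors[, pos, drop = FALSE]^2
  vals <- sapply(e_grid, function(e) {
    w <- exp(-(e - loglam)^2 / (2 * sigma^2))
    as.vector(Phi2 %*% w) / sum(w)
  })
  vals <- matrix(vals, nrow = g$n_nodes)
  structure(
    list(values = vals, kind = "wks",
         params = list(energies = e_grid, sigma = sigma,
                       sigma_scale = sigma_scale)),
    class = "qw_signature"
  )
}

#' @export
print.qw_signature <- function(x, ...) {
  cat(sprintf("<qw_signature> kind = %s, %d nodes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Signature distance between two nodes
#'
#' Euclidean distance between two node signature vectors, the edge
#' labelling function used when merging signature-attributed graphs.
#'
#' @param fu,fv numeric vectors of equal length.
#' @return nonnegative real.
#' @export
signature_edge_weight <- function(fu, fv) {
  if (length(fu) != length(fv))
    stop("signature vectors must have equal length")
  sqrt(sum((fu - fv)^2))
}
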