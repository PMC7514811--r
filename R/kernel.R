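#' Kernel configuration
#'
#' Bundles the choices that define a quantum-walk kernel evaluation:
#' the Hamiltonian of the merged graph, the averaging horizon (infinite
#' by default), the kernel variant, optional node-signature weighting,
#' and numerical settings.
#'
#' The `"pd"` variant is the provably positive-definite kernel: it
#' forces the Laplacian Hamiltonian, undirected inputs and the
#' constrained initial states, and is computed in closed form from the
#' two graphs' spectral distributions (see [kernel_pd_pair()]).
#'
#' @param hamiltonian `"laplacian"` (default), `"adjacency"` or
#'   `"normalised_laplacian"` for undirected graphs;
#'   `"directed_laplacian"` or `"directed_normalised_laplacian"` for
#'   directed graphs.
#' @param time `Inf` (default) for the infinite-time average, or a
#'   positive finite horizon `T`.
#' @param variant `"standard"` or `"pd"`.
#' @param signature `NULL` (no signature weighting), `"hks"` or
#'   `"wks"`.
#' @param signature_params list of arguments passed to the signature
#'   constructor ([heat_kernel_signature()] or
#'   [wave_kernel_signature()]).
#' @param weight_mode `"similarity"` or `"raw_distance"`; see
#'   [merge_graphs_weighted()].
#' @param degree_source `"merged"` or `"original"`; see
#'   [initial_states()].
#' @param degeneracy_tol passed to [spectral_decomposition()];
#'   `NULL` for the relative default.
#' @param log_base entropy logarithm base (default 2).
#' @param perturb fallback flag for regular graphs in the `"pd"`
#'   variant; see [constrained_initial_states()].
#' @return an object of class `qw_kernel_options`.
#' @export
kernel_options <- function(hamiltonian = "laplacian", time = Inf,
                           variant = c("standard", "pd"),
                           signature = NULL, signature_params = list(),
                           weight_mode = "similarity",
                           degree_source = "merged",
                           degeneracy_tol = NULL, log_base = 2,
                           perturb = FALSE) {
  variant <- match.arg(variant)
  hamiltonian <- match.arg(hamiltonian,
    c("laplacian", "adjacency", "normalised_laplacian",
      "directed_laplacian", "directed_normalised_laplacian"))
  if (!is.null(signature))
    signature <- match.arg(signature, c("hks", "wks"))
  if (variant == "pd") {
    if (hamiltonian != "laplacian")
      stop("the pd variant is defined for the Laplacian Hamiltonian only")
    if (is.finite(time))
      stop("the pd variant is an infinite-time kernel")
  }
  if (!(is.infinite(time) || (is.numeric(time) && time > 0)))
    stop("time must be Inf or a positive real")
  structure(
    list(hamiltonian = hamiltonian, time = time, variant = variant,
         signature = signature, signature_params = signature_params,
         weight_mode = weight_mode, degree_source = degree_source,
         degeneracy_tol = degeneracy_tol, log_base = log_base,
         perturb = perturb),
    class = "qw_kernel_options"
  )
}

compute_signature <- function(g, opts) {
  args <- c(list(g), opts$signature_params)
  switch(opts$signature,
         hks = do.call(heat_kernel_signature, args),
         wks = do.call(wave_kernel_signature, args))
}

#' Quantum-walk kernel between two graphs
#'
#' The full pipeline: merge the graphs with complete cross-connections
#' (optionally signature-weighted), prepare the constructive and
#' destructive degree-proportional initial states, evolve both walks
#' under the merged graph's Hamiltonian, time-average the states, and
#' return the quantum Jensen-Shannon divergence between the two
#' averages.  The more alike the graphs, the stronger the interference
#' contrast and the larger the value; isomorphic graphs attain 1.
#'
#' @param g1,g2 `qw_graph` objects of equal directedness, compatible
#'   with `opts$hamiltonian`.
#' @param opts a [kernel_options()] object.
#' @return kernel value in `[0, 1]`.
#' @examples
#' g <- er_graph(8, 0.4, seed = 5)
#' h <- isomorphic_copy(g, seed = 6)$graph
#' kernel_pair(g, h, kernel_options("laplacian"))
#' @export
kernel_pair <- function(g1, g2, opts = kernel_options()) {
  stop_not_graph(g1); stop_not_graph(g2)
  if (!inherits(opts, "qw_kernel_options"))
    stop("opts must be created by kernel_options()")
  if (opts$variant == "pd")
    return(kernel_pd_pair(g1, g2, perturb = opts$perturb,
                          degeneracy_tol = opts$degeneracy_tol,
                          log_base = opts$log_base))
  mg <- if (is.null(opts$signature)) {
    merge_graphs(g1, g2)
  } else {
    merge_graphs_weighted(g1, g2,
                          compute_signature(g1, opts),
                          compute_signature(g2, opts),
                          weight_mode = opts$weight_mode)
  }
  states <- initial_states(mg, degree_source = opts$degree_source)
  H <- graph_hamiltonian(mg$graph, opts$hamiltonian)
  spec <- spectral_decomposition(H, opts$degeneracy_tol)
  if (is.infinite(opts$time)) {
    rho_m <- infinite_time_density(states$psi_minus, spec)
    rho_p <- infinite_time_density(states$psi_plus, spec)
  } else {
    rho_m <- finite_time_density(states$psi_minus, spec, opts$time)
    rho_p <- finite_time_density(states$psi_plus, spec, opts$time)
  }
  qjsd(rho_m, rho_p, base = opts$log_base)
}

#' Shifted spectral distribution of a graph
#'
#' The discrete energy distribution a graph contributes to the
#' closed-form positive-definite kernel: atoms at the distinct
#' Laplacian eigenvalues of the graph shifted down by its own node
#' count `n`, with mass `2 <xi0| P_lambda |xi0>` at each atom, where
#' `xi0` is the mean-centred degree vector scaled to squared norm 1/2.
#' The constant-eigenvector component carries no mass because `xi0` is
#' centred, so the atom at the shifted zero eigenvalue has zero mass
#' and masses sum to 1.
#'
#' The shift makes the support depend on the graph's own size; two
#' graphs share an atom only where their shifted eigenvalues coincide,
#' so the kernel is sensitive to the number of nodes.
#'
#' @param g a non-regular undirected `qw_graph`.
#' @param other_size unused bookkeeping argument (the merged-graph
#'   eigenvalues equal these atoms shifted up by the total size);
#'   retained for documentation.
#' @param perturb fallback for regular graphs; see
#'   [constrained_initial_states()].
#' @param degeneracy_tol passed to [spectral_decomposition()].
#' @return a `qw_energy_dist` with `shift = n`.
#' @export
graph_spectral_distribution <- function(g, other_size = NULL,
                                        perturb = FALSE,
                                        degeneracy_tol = NULL) {
  stop_not_graph(g)
  if (g$directed)
    stop("the closed-form spectral distribution requires an undirected graph")
  d <- degrees(g)
  x <- d - mean(d)
  if (sqrt(sum(x^2)) < 1e-12 * max(1, max(abs(d)))) {
    if (!perturb)
      stop("graph is regular (constant degree vector): the constrained ",
           "initial state is unconstructible; see perturb = TRUE")
    d[1] <- d[1] + 1e-6
    x <- d - mean(d)
  }
  xi0 <- x / sqrt(sum(x^2)) / sqrt(2)
  spec <- spectral_decomposition(laplacian(g), degeneracy_tol)
  c0 <- as.vector(crossprod(spec$vectors, xi0))
  mass <- 2 * vapply(spec$groups, function(ix) sum(c0[ix]^2), numeric(1))
  new_energy_dist(spec$representatives - g$n_nodes, mass, shift = g$n_nodes)
}

merge_atoms <- function(support, probs, tol) {
  ord <- order(support)
  support <- support[ord]; probs <- probs[ord]
  grp <- integer(length(support))
  grp[1] <- 1L
  if (length(support) > 1) for (i in 2:length(support))
    grp[i] <- if (support[i] - support[i - 1] <= tol) grp[i - 1]
              else grp[i - 1] + 1L
  list(support = vapply(split(support, grp), mean, numeric(1)),
       probs = vapply(split(probs, grp), sum, numeric(1)))
}

#' Classical Jensen-Shannon divergence of two energy distributions
#'
#' `CJSD(f1, f2) = S((f1 + f2)/2) - S(f1)/2 - S(f2)/2` in bits.  The
#' supports of the two distributions are merged with a tolerance:
#' atoms whose locations agree within `support_tol` are treated as the
#' same outcome and their mixture masses added.
#'
#' @param f1,f2 `qw_energy_dist` objects.
#' @param support_tol atom-coincidence tolerance; default
#'   `1e-8 * max(1, largest absolute support value)`.
#' @param base logarithm base (default 2).
#' @return divergence in `[0, 1]` (for base 2).
#' @export
cjsd <- function(f1, f2, support_tol = NULL, base = 2) {
  if (!inherits(f1, "qw_energy_dist") || !inherits(f2, "qw_energy_dist"))
    stop("f1 and f2 must be qw_energy_dist objects")
  if (is.null(support_tol))
    support_tol <- 1e-8 * max(1, abs(f1$support), abs(f2$support))
  mix <- merge_atoms(c(f1$support, f2$support),
                     c(f1$probs, f2$probs) / 2, support_tol)
  entropy_from_probs(mix$probs, base) -
    (entropy_from_probs(f1$probs, base) +
       entropy_from_probs(f2$probs, base)) / 2
}

#' Positive-definite quantum-walk kernel (closed form)
#'
#' The infinite-time kernel with Laplacian Hamiltonian and constrained
#' initial states admits the closed form
#' `k(G1, G2) = 1 - CJSD(f1, f2)`, where `f1`, `f2` are the graphs'
#' shifted spectral distributions ([graph_spectral_distribution()]).
#' Because the classical Jensen-Shannon divergence is conditionally
#' negative definite, this kernel is positive definite: Gram matrices
#' built from it are positive semi-definite.  No merged graph has to be
#' constructed, and each graph's distribution can be precomputed once
#' per dataset.
#'
#' @param g1,g2 non-regular undirected `qw_graph` objects.
#' @param perturb fallback for regular inputs; see
#'   [constrained_initial_states()].
#' @param degeneracy_tol,support_tol numerical tolerances.
#' @param log_base entropy logarithm base; the default 2 gives values
#'   in `[0, 1]`.
#' @return kernel value in `[0, 1]`.
#' @export
kernel_pd_pair <- function(g1, g2, perturb = FALSE, degeneracy_tol = NULL,
                           support_tol = NULL, log_base = 2) {
  f1 <- graph_spectral_distribution(g1, perturb = perturb,
                                    degeneracy_tol = degeneracy_tol)
  f2 <- graph_spectral_distribution(g2, perturb = perturb,
                                    degeneracy_tol = degeneracy_tol)
  d <- cjsd(f1, f2, support_tol = support_tol, base = 2)
  if (log_base == 2) 1 - d else (1 - d) * log(2, base = log_base)
}

#' Gram matrix of pairwise kernel values
#'
#' Evaluates the kernel on every pair of a graph list.  For the `"pd"`
#' variant each graph's spectral distribution is computed once and
#' reused across pairs.  A failing pair is recorded, its entry set to
#' `NA`, and a warning raised; the matrix is completed either way.
#'
#' @param graphs list of `qw_graph` objects of homogeneous
#'   directedness.
#' @param opts a [kernel_options()] object.
#' @param ids optional character identifiers for the graphs.
#' @return an object of class `qw_gram`: the symmetric matrix of kernel
#'   values with attributes `options`, `ids` and (if any) `errors`.
#' @export
gram_matrix <- function(graphs, opts = kernel_options(), ids = NULL) {
  if (!is.list(graphs) || length(graphs) == 0)
    stop("graphs must be a nonempty list")
  lapply(graphs, stop_not_graph)
  dirs <- vapply(graphs, function(g) g$directed, logical(1))
  if (length(unique(dirs)) > 1)
    stop("graphs must be homogeneously directed or undirected")
  k <- length(graphs)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(k))
  K <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  errors <- list()
  if (opts$variant == "pd") {
    dists <- lapply(graphs, function(g)
      tryCatch(graph_spectral_distribution(g, perturb = opts$perturb,
                                           degeneracy_tol = opts$degeneracy_tol),
               error = function(e) e))
    for (i in seq_len(k)) for (j in i:k) {
      if (inherits(dists[[i]], "error") || inherits(dists[[j]], "error")) {
        bad <- if (inherits(dists[[i]], "error")) dists[[i]] else dists[[j]]
        errors[[paste(ids[i], ids[j], sep = ":")]] <- conditionMessage(bad)
        next
      }
      v <- 1 - cjsd(dists[[i]], dists[[j]])
      K[i, j] <- K[j, i] <- v
    }
  } else {
    for (i in seq_len(k)) for (j in i:k) {
      v <- tryCatch(kernel_pair(graphs[[i]], graphs[[j]], opts),
                    error = function(e) e)
      if (inherits(v, "error")) {
        errors[[paste(ids[i], ids[j], sep = ":")]] <- conditionMessage(v)
      } else {
        K[i, j] <- K[j, i] <- v
      }
    }
  }
  if (length(errors) > 0)
    warning(sprintf("%d graph pair(s) failed; entries set to NA",
                    length(errors)))
  structure(K, class = c("qw_gram", "matrix"), options = opts,
            ids = ids, errors = if (length(errors)) errors else NULL)
}

#' @export
print.qw_gram <- function(x, ...) {
  cat(sprintf("<qw_gram> %d x %d kernel matrix (%s variant, %s)\n",
              nrow(x), ncol(x), attr(x, "options")$variant,
              attr(x, "options")$hamiltonian))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
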