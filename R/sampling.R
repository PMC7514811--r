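#' @section Sampling-based kernel computation:
#' On quantum hardware the kernel would be computed by preparing many
#' copies of the initial pure state, measuring the Hamiltonian as an
#' observable, and feeding the observed energies to a discrete entropy
#' estimator.  The functions here simulate that scheme classically:
#' energies are drawn from the exact measurement distribution and
#' entropies estimated from the samples.  One sample set per graph
#' suffices for all pairwise kernel evaluations of the
#' positive-definite variant; pooling two equally sized sets estimates
#' the mixture entropy.
#' @name qwkernel-sampling
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Sample energy measurements from a pure state
#'
#' Draws `n` i.i.d. energy observations from the measurement
#' distribution of the Hamiltonian in the given pure state
#' ([mixing_spectrum()] with zero shift).  Degenerate eigenvalues are a
#' single outcome, as for a physical measurement of the observable.
#' Reproducible given `seed`; the caller's RNG state is left untouched.
#'
#' @param state unit-norm amplitude vector.
#' @param spec a [spectral_decomposition()] of the Hamiltonian.
#' @param n number of samples (at least 1).
#' @param seed integer seed.
#' @return an object of class `qw_samples` with fields `samples`, `n`
#'   and `seed`.
#' @export
sample_energies <- function(state, spec, n, seed) {
  if (n < 1) stop("n must be at least 1")
  dist <- mixing_spectrum(state, spec, shift = 0)
  idx <- with_seed(seed,
    sample.int(length(dist$support), size = n, replace = TRUE,
               prob = dist$probs))
  structure(list(samples = dist$support[idx], n = as.integer(n),
                 seed = as.integer(seed)),
            class = "qw_samples")
}

#' @export
print.qw_samples <- function(x, ...) {
  cat(sprintf("<qw_samples> %d energy samples (seed %d)\n", x$n, x$seed))
  invisible(x)
}

sample_values <- function(s) {
  if (inherits(s, "qw_samples")) s$samples else as.numeric(s)
}

#' Entropy estimate from energy samples
#'
#' Plug-in (maximum-likelihood) Shannon entropy of the empirical
#' distribution of the samples, in bits, optionally with the
#' Miller-Madow bias correction `(k - 1) / (2 n ln 2)` where `k` is the
#' number of distinct observed outcomes.  Sample values closer than
#' `tol` are treated as the same outcome.
#'
#' @param s a `qw_samples` object or numeric vector of energy samples.
#' @param estimator `"plugin"` (default) or `"miller_madow"`.
#' @param tol outcome-coincidence tolerance; default
#'   `1e-8 * max(1, largest absolute sample)`.
#' @return entropy estimate in bits.
#' @export
entropy_estimate <- function(s, estimator = c("plugin", "miller_madow"),
                             tol = NULL) {
  estimator <- match.arg(estimator)
  x <- sample_values(s)
  if (length(x) < 1) stop("need at least one sample")
  if (is.null(tol)) tol <- 1e-8 * max(1, abs(x))
  counts <- merge_atoms(sort(x), rep(1, length(x)), tol)$probs
  p <- counts / length(x)
  H <- entropy_from_probs(p, 2)
  if (estimator == "miller_madow")
    H <- H + (length(p) - 1) / (2 * length(x) * log(2))
  H
}

#' Sampling-based estimate of the positive-definite kernel
#'
#' Simulates the fully quantum computation of the closed-form kernel:
#' each graph's shifted spectral distribution is sampled once
#' (`n_per_graph` energy measurements), the two individual entropies
#' are estimated from the two sets, the mixture entropy from their
#' pooled union (the two sets have equal size, so pooling weights the
#' mixture equally), and the kernel estimate is
#' `1 - [S_mix - S(f1)/2 - S(f2)/2]`.  The estimate converges to
#' [kernel_pd_pair()] as `n_per_graph` grows.
#'
#' @param g1,g2 non-regular undirected `qw_graph` objects.
#' @param n_per_graph samples drawn per graph.
#' @param seed integer seed (the second graph uses `seed + 1`).
#' @param estimator entropy estimator; see [entropy_estimate()].
#' @param perturb fallback for regular inputs.
#' @return list with `estimate`, `exact` (the closed-form value) and
#'   the two `qw_samples` sets.
#' @export
kernel_estimate_sampled <- function(g1, g2, n_per_graph, seed,
                                    estimator = "plugin",
                                    perturb = FALSE) {
  f1 <- graph_spectral_distribution(g1, perturb = perturb)
  f2 <- graph_spectral_distribution(g2, perturb = perturb)
  draw <- function(dist, s) {
    idx <- with_seed(s, sample.int(length(dist$support),
                                   size = n_per_graph, replace = TRUE,
                                   prob = dist$probs))
    structure(list(samples = dist$support[idx],
                   n = as.integer(n_per_graph), seed = as.integer(s)),
              class = "qw_samples")
  }
  s1 <- draw(f1, seed)
  s2 <- draw(f2, seed + 1L)
  S1 <- entropy_estimate(s1, estimator)
  S2 <- entropy_estimate(s2, estimator)
  Smix <- entropy_estimate(c(s1$samples, s2$samples), estimator)
  list(estimate = 1 - (Smix - S1 / 2 - S2 / 2),
       exact = 1 - cjsd(f1, f2),
       samples1 = s1, samples2 = s2)
}
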