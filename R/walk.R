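#' @section Walk evolution and density matrices:
#' A pure state is a complex amplitude vector of unit Euclidean norm
#' over the nodes; the squared moduli are the node occupation
#' probabilities.  Evolution follows the Schrodinger equation with the
#' graph Hamiltonian, solved in the eigenbasis.  Time-averaging the
#' rank-1 projector of the evolving state gives a mixed state (density
#' matrix); the infinite-time average is the pinching of the initial
#' projector by the Hamiltonian's eigenprojectors.
#' @name qwkernel-walks
NULL

check_state <- function(state, spec) {
  if (!inherits(spec, "qw_spectrum"))
    stop("expected a qw_spectrum (see spectral_decomposition())")
  if (length(state) != nrow(spec$vectors))
    stop("state dimension does not match the Hamiltonian")
  nrm <- sqrt(sum(Mod(state)^2))
  if (abs(nrm - 1) > 1e-10)
    stop(sprintf("state is not normalised: ||psi|| = %.12f", nrm))
  invisible(state)
}

new_density <- function(M) {
  structure(list(matrix = M), class = "qw_density")
}

#' @export
print.qw_density <- function(x, ...) {
  cat(sprintf("<qw_density> %d x %d\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Evolve a pure state under a Hamiltonian
#'
#' `psi_t = Phi exp(-i Lambda t) t(Phi) psi_0`, the unitary solution of
#' the Schrodinger evolution for time `t`.  The norm is preserved.
#'
#' @param state complex (or numeric) unit-norm amplitude vector.
#' @param spec a [spectral_decomposition()] of the Hamiltonian.
#' @param t real time.
#' @return complex amplitude vector.
#' @export
evolve <- function(state, spec, t) {
  check_state(state, spec)
  if (t == 0) return(as.complex(state))
  c0 <- crossprod(spec$vectors, state)
  as.vector(spec$vectors %*% (exp(-1i * spec$values * t) * c0))
}

# (1 - exp(-i x)) / (i x) with the removable singularity at 0 filled in
sinc_phase <- function(x) {
  out <- rep(1 + 0i, length(x))
  nz <- abs(x) > 1e-300
  out[nz] <- (1 - exp(-1i * x[nz])) / (1i * x[nz])
  out
}

#' Finite-time average density matrix
#'
#' The uniform mixture of the walk's pure states over `[0, T]`,
#' `rho_T = (1/T) integral_0^T |psi_t><psi_t| dt`, computed in closed
#' form in the eigenbasis: with `c = t(Phi) psi_0` the eigenbasis entry
#' `(j, k)` is `c_j * Conj(c_k) * (1 - exp(-i D T)) / (i D T)` where
#' `D = lambda_j - lambda_k` (and 1 on the diagonal).  No numerical
#' quadrature is involved.
#'
#' @param state unit-norm amplitude vector (the walk's initial state).
#' @param spec a [spectral_decomposition()] of the Hamiltonian.
#' @param T positive averaging horizon.
#' @return a `qw_density` (Hermitian, unit trace, positive
#'   semi-definite).
#' @export
finite_time_density <- function(state, spec, T) {
  check_state(state, spec)
  if (!is.numeric(T) || length(T) != 1 || T <= 0)
    stop("T must be a positive real")
  c0 <- as.vector(crossprod(spec$vectors, state))
  delta <- outer(spec$values, spec$values, "-")
  R <- outer(c0, Conj(c0)) * sinc_phase(delta * T)
  M <- spec$vectors %*% R %*% t(spec$vectors)
  new_density((M + Conj(t(M))) / 2)
}

#' Infinite-time average density matrix
#'
#' The limit of [finite_time_density()] for `T -> Inf`:
#' `rho_inf = sum_lambda P_lambda |psi_0><psi_0| P_lambda`, summed over
#' the distinct eigenvalues of the Hamiltonian with `P_lambda` the full
#' eigenspace projector.  This "pinching" of the initial projector
#' commutes with the Hamiltonian and is idempotent as a map.
#'
#' @inheritParams finite_time_density
#' @return a `qw_density`.
#' @export
infinite_time_density <- function(state, spec) {
  check_state(state, spec)
  c0 <- as.vector(crossprod(spec$vectors, state))
  R <- outer(c0, Conj(c0))
  grp <- integer(length(spec$values))
  for (i in seq_along(spec$groups)) grp[spec$groups[[i]]] <- i
  R[outer(grp, grp, "!=")] <- 0
  M <- spec$vectors %*% R %*% t(spec$vectors)
  new_density((M + Conj(t(M))) / 2)
}

new_energy_dist <- function(support, probs, shift = 0) {
  ord <- order(support)
  structure(list(support = support[ord], probs = probs[ord], shift = shift),
            class = "qw_energy_dist")
}

#' @export
print.qw_energy_dist <- function(x, ...) {
  cat(sprintf("<qw_energy_dist> %d atoms, shift = %g\n",
              length(x$support), x$shift))
  invisible(x)
}

#' Energy measurement distribution of a pure state
#'
#' Measuring the Hamiltonian as an observable on the pure state
#' `|psi_0>` yields one of the distinct eigenvalues `lambda`, with
#' probability `<psi_0| P_lambda |psi_0>`.  These probabilities equal
#' the nonzero eigenvalues of the infinite-time average density matrix,
#' which is why the von Neumann entropy of the infinite-time average
#' equals the Shannon entropy of this distribution.
#'
#' @inheritParams finite_time_density
#' @param shift real offset subtracted from the eigenvalue support
#'   (bookkeeping for the closed-form kernel; 0 by default).
#' @return a `qw_energy_dist` with fields `support` (ascending shifted
#'   eigenvalue representatives), `probs` and `shift`.
#' @export
mixing_spectrum <- function(state, spec, shift = 0) {
  check_state(state, spec)
  c0 <- as.vector(crossprod(spec$vectors, state))
  w <- Mod(c0)^2
  probs <- vapply(spec$groups, function(ix) sum(w[ix]), numeric(1))
  new_energy_dist(spec$representatives - shift, probs, shift)
}

entropy_from_probs <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Von Neumann / Shannon entropy
#'
#' For a density matrix, `-tr(rho log rho)`, i.e. the Shannon entropy of
#' its eigenvalue spectrum; for an energy distribution, the Shannon
#' entropy of its atom probabilities.  Logarithms are base 2 by default
#' (entropy in bits), the convention under which the quantum
#' Jensen-Shannon divergence is bounded by 1; pass `base = exp(1)` for
#' nats.  `0 log 0` is taken as 0.
#'
#' @param x a `qw_density`, a Hermitian matrix, or a `qw_energy_dist`.
#' @param base logarithm base (default 2).
#' @return nonnegative real.
#' @export
von_neumann_entropy <- function(x, base = 2) {
  if (inherits(x, "qw_energy_dist")) {
    if (abs(sum(x$probs) - 1) > 1e-8)
      stop("energy distribution probabilities must sum to 1")
    return(entropy_from_probs(x$probs, base))
  }
  M <- if (inherits(x, "qw_density")) x$matrix else as.matrix(x)
  tr <- sum(Re(diag(M)))
  if (abs(tr - 1) > 1e-8)
    stop(sprintf("density matrix trace is %.10f, not 1", tr))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("matrix is not positive semi-definite (min eigenvalue %.3e)",
                 min(ev)))
  entropy_from_probs(pmax(ev, 0), base)
}

#' Quantum Jensen-Shannon divergence
#'
#' `QJSD(rho, sigma) = S((rho + sigma)/2) - S(rho)/2 - S(sigma)/2`,
#' symmetric and bounded in `[0, 1]` with base-2 entropies.  It is 0
#' exactly when the states coincide and 1 exactly when their supports
#' are orthogonal subspaces.
#'
#' @param rho,sigma `qw_density` objects (or Hermitian unit-trace
#'   matrices) of equal dimension.
#' @param base logarithm base (default 2; the `[0, 1]` bound holds for
#'   base 2).
#' @return real divergence value.
#' @export
qjsd <- function(rho, sigma, base = 2) {
  Mr <- if (inherits(rho, "qw_density")) rho$matrix else as.matrix(rho)
  Ms <- if (inherits(sigma, "qw_density")) sigma$matrix else as.matrix(sigma)
  if (!all(dim(Mr) == dim(Ms)))
    stop("density matrices must have equal dimensions")
  von_neumann_entropy(new_density((Mr + Ms) / 2), base) -
    (von_neumann_entropy(new_density(Mr), base) +
       von_neumann_entropy(new_density(Ms), base)) / 2
}
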