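---
title: "Measuring graph similarity with interfering quantum walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring graph similarity with interfering quantum walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qwkernel)
```

## The model

A continuous-time quantum walk on a graph is the quantum analogue of a
classical diffusion: the walker's state is a complex amplitude vector
$|\psi_t\rangle$ over the nodes, evolving as
$|\psi_t\rangle = e^{-iHt}|\psi_0\rangle$ under a symmetric operator
$H$ built from the graph.  Unlike a classical walk, amplitudes
interfere: walks started in carefully chosen superpositions behave very
differently on symmetric and asymmetric structures, and that difference
is what this package turns into a similarity measure.

Given two graphs $G_1$ ($n$ nodes) and $G_2$ ($m$ nodes), we build a
*merged graph*: the disjoint union of the two, plus an undirected edge
between every node of $G_1$ and every node of $G_2$
(`merge_graphs()`).  On this arena we prepare two walks with
degree-proportional amplitudes (`initial_states()`):

* $|\psi_0^{+}\rangle \propto \sum_{u} d_u |u\rangle$ — equal phase
  everywhere, engineered for *constructive* interference;
* $|\psi_0^{-}\rangle \propto \sum_{u \in V_1} d_u |u\rangle -
  \sum_{v \in V_2} d_v |v\rangle$ — opposite phase on the two sides,
  engineered for *destructive* interference.

Each walk's evolution is summarised by the infinite-time average of its
rank-1 projector,
$\rho_\infty = \sum_{\lambda} P_\lambda\,
|\psi_0\rangle\langle\psi_0|\, P_\lambda$, where $P_\lambda$ projects
on the eigenspace of each distinct eigenvalue of $H$
(`infinite_time_density()`; a finite-horizon average
$\rho_T = \frac1T \int_0^T |\psi_t\rangle\langle\psi_t|\,dt$ is also
available in closed form).  The kernel value is the quantum
Jensen-Shannon divergence between the two averages,

$$k(G_1,G_2) \;=\; \mathrm{QJSD}(\rho_\infty^-, \rho_\infty^+)
  \;=\; S\!\Big(\tfrac{\rho^-_\infty+\rho^+_\infty}{2}\Big)
  - \tfrac12 S(\rho^-_\infty) - \tfrac12 S(\rho^+_\infty),$$

with $S$ the von Neumann entropy.  The more alike the graphs, the more
symmetric the merged structure, the stronger the interference contrast
between the two walks and the larger the divergence: a pair of
isomorphic graphs attains exactly 1.

```{r iso}
g <- er_graph(10, 0.4, seed = 1, require_connected = TRUE)
copy <- isomorphic_copy(g, seed = 2)$graph
kernel_pair(g, copy, kernel_options("laplacian"))
```

## Choices of Hamiltonian

Any symmetric operator encoding the merged graph can drive the walk.
For undirected inputs the package offers the adjacency matrix, the
combinatorial Laplacian $L = D - A$ (the default), and the symmetric
normalised Laplacian $D^{-1/2} L D^{-1/2}$.  We use the symmetric
normalisation throughout: a one-sided normalisation
($D^{-1/2} L D^{1/2}$) is similar to it but not symmetric, and a
quantum walk needs a Hermitian generator.  Isolated nodes use the
convention $D^{-1/2}_{uu} = 0$.

Directed graphs cannot use the (asymmetric) adjacency matrix, so the
package builds Chung's directed Laplacians from the random-walk
transition matrix $M_{uv} = A_{uv}/d^{out}_u$ and its stationary
distribution $\pi$:
$L = \Pi - (\Pi M + M^\top\Pi)/2$ and
$\tilde L = I - (\Pi^{1/2}M\Pi^{-1/2} + \Pi^{-1/2}M^\top\Pi^{1/2})/2$,
with $\Pi = \mathrm{diag}(\pi)$.  Both are symmetric and positive
semi-definite, so they are valid Hamiltonians.  $\pi$ exists uniquely
only on strongly connected graphs; this is a hard precondition for
standalone directed Laplacians, but the kernel pipeline never violates
it, because the merged graph's cross edges are bidirectional and make
it strongly connected whenever both sides are nonempty.  We compute
$\pi$ by power iteration on the lazy chain $(I+M)/2$ (tolerance
$10^{-12}$ on $\lVert\pi M - \pi\rVert_1$, at most $10^5$ iterations):
the lazy chain has the same fixed point but is aperiodic, so
convergence does not require any aperiodicity assumption on the graph.

## Node signatures and weighted merging

Structural node descriptors can be folded into the kernel.  The heat
kernel signature $\mathrm{HKS}(u,t) = \sum_k e^{-\lambda_k t}
\phi_k(u)^2$ and the wave kernel signature (a log-energy Gaussian band
filter over the spectrum) are computed on the *original* graphs from
the Laplacian eigenpairs.  The merged graph then becomes a complete
weighted graph in which every pair of distinct nodes — within either
side as well as across — is connected with a weight derived from the
Euclidean distance $\omega$ between the two nodes' signatures
(`merge_graphs_weighted()`).  The original edges are not lost: they are
encoded in the signatures themselves.

$\omega$ is a *distance*, yet the natural reading of a heavy edge is
"these nodes are similar".  The package therefore defaults to a
self-tuned Gaussian similarity $w = \exp(-\omega^2/2s^2)$ with $s$ the
median pairwise distance, and exposes `weight_mode = "raw_distance"`
for the literal alternative.  Neither choice is claimed to be canonical;
both keep the isomorphism-implies-1 property.

Signature defaults: 10 HKS times log-spaced over
$[4\ln 10/\lambda_{\max},\, 4\ln 10/\lambda^{+}_{\min}]$ (the
convention of the signature literature), 10 WKS energies spanning the
log-spectrum with bandwidth equal to one grid step.  Both are
configurable through `signature_params`.

## The positive-definite variant

With the Laplacian Hamiltonian and initial states whose side
restrictions $\xi_0, \chi_0$ are mean-centred
($\langle \mathbf 1|\xi_0\rangle = \langle \mathbf 1|\chi_0\rangle = 0$)
and carry squared norm $\tfrac12$ each
(`constrained_initial_states()`), the merged-graph eigensystem can be
written out completely: centred eigenvectors of $L_1$ embed as
$(v, 0)$ with eigenvalue $\lambda + m$, those of $L_2$ as $(0, w)$
with eigenvalue $\lambda + n$, and the two remaining eigenpairs are
the constant vector (eigenvalue 0) and $(m\mathbf 1_n, -n\mathbf 1_m)$
(eigenvalue $m+n$).  The kernel then collapses to

$$k(G_1,G_2) = 1 - \mathrm{CJSD}(f_1, f_2),$$

where $f_i$ is a discrete distribution on graph $i$'s distinct
Laplacian eigenvalues *shifted down by its own node count*, with mass
$2\langle\xi_0|P_\lambda|\xi_0\rangle$ per atom
(`graph_spectral_distribution()`), and CJSD is the classical
Jensen-Shannon divergence.  Since CJSD is conditionally negative
definite, the kernel is positive definite — Gram matrices are PSD and
safe for any kernel method.  The closed form needs one
eigendecomposition per *graph* rather than per *pair*, so Gram-matrix
construction is markedly cheaper (`gram_matrix()` exploits this).

Two consequences deserve emphasis:

* **Regular graphs are excluded.**  A constant degree vector centres to
  zero, so the constrained state does not exist.  The package refuses
  such inputs rather than silently perturbing them;
  `perturb = TRUE` opts into a documented deterministic fallback
  ($10^{-6}$ added to the first node's degree before centering).
* **The kernel is spectrum-exact.**  Two graphs share an atom only
  where their shifted eigenvalue supports coincide (within
  `support_tol`, default $10^{-8}\max(1,\rho)$).  Graphs with
  continuous-valued, non-coincident spectra — e.g. generic weighted or
  random graphs of different sizes — have disjoint supports, CJSD
  $= 1$, and kernel value $\approx 0$ regardless of any structural
  resemblance.  Sensible behaviour requires graph families with
  substantially shared spectra (small unweighted graphs with symmetric
  substructures).  The shift by the graph's own size, taken exactly as
  the theory prescribes, further restricts atom sharing across sizes.
  The standard variant does not have this property and is the default
  for data analysis.

The package's central correctness oracle runs both routes — the closed
form and the explicit merged-graph pinching — and verifies they agree
to $10^{-8}$ on dozens of random pairs.

## Entropy notation and the logarithm base

All entropies are base 2 by default.  This is the convention under
which the QJSD is bounded by 1 with equality exactly at orthogonal
supports, the isomorphic-pair kernel value is exactly 1, and the
closed form reads $1 - \mathrm{CJSD}$.  Natural-log output is available
via `base`/`log_base` arguments (a global factor $\ln 2$).

The infinite-time average treats $\tilde\Lambda(H)$ as the set of
*distinct* eigenvalues with $P_\lambda$ the full eigenspace projector.
Numerically, "distinct" is decided by single-linkage clustering of the
sorted eigenvalues with a relative gap threshold
$10^{-9}\max(1, \rho(H))$ (`spectral_decomposition()`): exact
degeneracies computed in floating point split at the $10^{-14}$ level
and must be re-merged, while genuinely separate eigenvalues of sensible
graphs sit far above the threshold.

## The sampling scheme

On quantum hardware the kernel would be estimated by preparing many
copies of the initial state and measuring the energy.  The probability
of observing the energy level $\lambda$ is
$\langle\psi_0|P_\lambda|\psi_0\rangle$ — exactly the spectrum of
$\rho_\infty$ — so the von Neumann entropy of the infinite-time average
equals the Shannon entropy of the measurement record.
`sample_energies()` simulates the measurements,
`entropy_estimate()` offers the plug-in and Miller-Madow estimators
(the bias-corrected estimators for the under-sampled regime are a
named extension point, not implemented), and
`kernel_estimate_sampled()` assembles the kernel estimate, drawing one
sample set per graph and pooling the two equal-sized sets to estimate
the mixture entropy.  At $10^4$ samples per graph the estimate sits
within a few hundredths of the exact value on the fixture pairs the
tests use.

## The synthetic generators

All inputs for tests and checks are generated in code
(Erdős–Rényi graphs, seeded isomorphic copies, root-oriented random
trees, Hamiltonian-cycle-based strongly connected digraphs); nothing is
downloaded.  `planted_two_class()` provides labelled datasets with a
controlled signal:

* *undirected mode*: two Erdős–Rényi densities (defaults 0.30 vs
  0.45 — far enough apart that a density-sensitive method should
  separate them at small sample sizes, close enough that a broken one
  will not);
* *directed mode*: both classes share identical undirected skeletons
  (density 0.30), and only the arc orientations differ — class 1
  orients every edge along a random topological order (acyclic
  feed-forward flow), class 2 orients each edge independently at
  random.  Symmetrization maps paired graphs of the two classes to
  *identical* matrices, so any symmetrized pipeline is provably at
  chance on paired data, while the directed Laplacians retain the
  orientation statistics.  This makes "directionality carries class
  signal" a testable property of the code rather than a claim about
  external data.

What the generators do *not* emulate: degree heterogeneity and
community structure of real molecular or biological networks,
node/edge attributes, and the specific construction of
time-lagged-correlation brain networks.  A passing suite therefore
demonstrates the advertised analytic properties (boundedness,
isomorphism saturation, positive definiteness, dual-route agreement,
sampling consistency) and the mechanics of the classification
pipeline — not classification accuracy on any real dataset.

## The classification harness

`cross_validate()` implements the evaluation protocol used with
precomputed graph kernels: a C-SVM on the Gram matrix, 10-fold
stratified cross-validation, the constant $C$ tuned independently for
each held-out fold by an inner 5-fold cross-validation restricted to
the training folds (grid $10^{-3},\dots,10^3$; ties go to the smaller
$C$), repeated over seeded random partitions, reported as mean
accuracy ± standard error over repetitions.  The inner protocol and
grid are this package's defaults, stated here because the protocol
itself does not pin them down.  A structural test poisons the held-out
rows and columns of the Gram matrix and verifies the tuning result is
unchanged — no test-fold leakage.

Standard-variant kernel matrices may be indefinite; they are passed to
the SVM as-is (mirroring common practice), with `clip = TRUE`
available to project onto the PSD cone first.

## Numerical choices, sizes, limitations

* Eigendecompositions use dense symmetric LAPACK routines; the
  finite-time average is evaluated in closed form in the eigenbasis
  ($\rho_T$ entry-wise via $(1-e^{-i\Delta T})/(i\Delta T)$), with no
  quadrature error.
* Self-checks in the test suite run on graphs of 4–30 nodes, Gram
  matrices up to $40\times 40$, $10$–$10^2$ CV repetitions, and up to
  $10^5$ energy samples — sizes at which every analytic identity can
  be verified to tight tolerances in seconds while still exercising
  degenerate spectra and both directedness regimes.
* Dense matrices cap practical graph sizes at a few thousand nodes;
  the per-pair eigendecomposition of the standard variant makes large
  Gram matrices the dominant cost ($O(k^2 (n+m)^3)$).
* Multigraphs, self-loops, negative weights and complex (magnetic)
  Hamiltonians are out of scope.  Directed-graph support requires the
  Chung construction; alternative directed Laplacians are not
  implemented.
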