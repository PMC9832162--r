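---
title: "Epidemic models on multilayer contact networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epidemic models on multilayer contact networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilayer)
```

## The modelling problem

Real contact networks mix interaction types with very different chances of
passing an infection: household contacts, workplace contacts, brief public
encounters. `epilayer` models a population of `N` individuals whose contacts
are split into `n` *layers* (edge types), layer `i` carrying its own
transmissibility. Only the per-layer degree distributions are needed — not
the explicit graph — which is what makes the approach usable in practice,
since degree distributions can be estimated from survey data while full
contact graphs cannot.

Two complementary frameworks are implemented, linked by a common object, the
**reproduction matrix** (R-matrix):

1. a *late-stage* (percolation-style) model that computes the probability
   that a vertex escapes infection over the whole outbreak, and
2. *dynamic* SIR models — a vertex-level ODE system on an explicit graph and
   a degree-based mean-field system that reduces exactly to `n` equations.

Stochastic simulators (configuration-model sampling, bond percolation,
event-driven Gillespie SIR) provide independent validation of the mean-field
predictions.

## Generating-function machinery

Layer `i` has degree pmf $P_i(k)$ with pgf $G_i(x) = \sum_k P_i(k)x^k$.
Layers are independent, so the joint degree pgf factorises,
$G(x_1,\dots,x_n) = \prod_i G_i(x_i)$. Following a random layer-`i` edge,
the vertex reached has *excess* (onward) degrees distributed as
$\tilde P_i(k_1,\dots,k_n) = (k_i+1)P_i(k_i+1)\prod_{j\ne i}P_j(k_j)/\mathbf E(k_i)$,
with pgf
$$\tilde G_i(x) = \frac{G_i'(x_i)}{G_i'(1)}\prod_{j \ne i} G_j(x_j),$$
and the whole-network excess pgf $\tilde G$ is their mean-degree-weighted
mixture. The susceptibility-weighted variant $\tilde H_i$ reweights
$\tilde P_i$ by the initial susceptibility of the reached vertex; with a
degree-independent susceptibility $s(0)$ it collapses to
$s(0)\,x_i \tilde G_i(x)$.

The central threshold objects are the $n \times n$ matrices
$$\mathcal R^{\tilde G}_{ij} = T_j\,\partial_{x_j} \tilde G_i\big|_{x=1},
  \qquad
  \mathcal R^{\tilde H}_{ij} = T_j\,\partial_{x_j} \tilde H_i\big|_{x=1}.$$
Entry $(i,j)$ counts expected onward layer-`j` transmissions from a vertex
itself reached along layer `i`. Row sums of $\mathcal R^{\tilde G}$ give the
per-layer reproduction numbers $R_0(i)$, and
$R_0 = \sum_i \mathbf E(k_i) R_0(i) / \mathbf E(k)$. With everyone initially
susceptible, $\mathcal R^{\tilde H} = \operatorname{diag}(T) +
\mathcal R^{\tilde G}$. Both identities are enforced in the test suite at
`1e-10`/`1e-12`.

**Orientation.** Some published worked examples print the transpose of this
entry convention. All spectral quantities (the epidemic threshold is the
spectral radius crossing 1) are transposition-invariant, so nothing
downstream depends on the choice; `r_matrix()` documents the convention and
the tests pin it down via finite-difference gradients.

## Late-stage model

`q_i` is the probability that a given layer-`i` edge never delivers the
infection: either the edge fails to transmit (probability `1 - T_i`) or the
far vertex itself escaped, giving the fixed-point system
$$q_i = 1 - T_i + T_i\,\tilde G_i(q_1,\dots,q_n).$$
A vertex of joint degree `k` escapes with probability $\prod_i q_i^{k_i}$;
averaging gives the escape probability $\mathbf P = G(q)$.

**Root selection.** The map is componentwise monotone on $[0,1]^n$ and
$q = \mathbf 1$ is always a root. `solve_percolation()` iterates from
$q = 0$, producing a nondecreasing sequence that converges to the *least*
fixed point — a deterministic, derivative-free branch choice. "No outbreak"
is declared when the least fixed point is within `1e-8` of all-ones.
Optional relaxation (damping halved on detected oscillation) guards the
slow, near-critical regime; the sup-norm residual tolerance defaults to
`1e-12`.

**Thresholds.** `scan_transition()` follows the spectral radius
$\lambda(t)$ of $\mathcal R^{\tilde G}$ along a parameter path and bisects
$\lambda(t) - 1$ to a bracket below `1e-6` — a numerical detection of the
unit-eigenvalue condition, not a symbolic bifurcation analysis. For a single
layer, `near_critical_slope()` returns the coefficient
$c = 2G'(1)/(\tilde G''(1) T_c^2)$ of the linear law
$1 - \mathbf P \approx c\,(T - T_c)$ just above $T_c = 1/\tilde G'(1)$; the
expansion is degenerate when $\tilde G''(1) = 0$ (e.g. all degrees 2, where
no finite-`T` transition exists at all).

## Vertex-level SIR on an explicit graph

On a known multilayer graph, `integrate_sir()` solves, per vertex,
$$\dot s_v = -s_v \sum_i \beta_i \sum_w A^i_{vw} x_w, \qquad
  \dot x_v = -\gamma x_v - \dot s_v, \qquad r_v = 1 - s_v - x_v,$$
eliminating `r` by conservation so the state has dimension `2N` and
compartment sums hold exactly. The quantity
$H(v) = s_v \exp\big(\gamma^{-1}\sum_i \beta_i \sum_w A^i_{vw} r_w\big)$
is a first integral of the exact flow, so its drift is a pure integrator
diagnostic: at the default `lsodar` tolerances (`rtol 1e-8`, `atol 1e-10`)
it stays below `1e-6`. Integration stops early once total infection falls
below `1e-10`.

The long-time limit satisfies the final-size system
$r_v = 1 - s_v(0)\exp\big(-\sum_i (\beta_i/\gamma) \sum_w A^i_{vw} r_w\big)$,
solved by `final_size()` by monotone iteration *from* `r = 1 - s0`, so a
seeded initial condition lands on the nontrivial root deterministically.
With `s0` identically 1 that start *is* the trivial root; `interior_eps`
reproduces the interior-start argument explicitly. Every solution obeys
$r_v \le 1 - s_v(0)e^{-R(v)}$ with
$R(v) = \sum_i (\beta_i/\gamma) k_i(v)$ (`final_size_bound()`).

**Seeding.** The model itself does not fix how an outbreak is initiated;
the default seeds every vertex with `x_v(0) = 1e-5`, `r_v(0) = 0`, the
conventional infinitesimal-seed choice for mean-field SIR.

## Degree-based mean-field SIR and its exact reduction

Grouping vertices by joint degree gives one compartment triple per degree
class, driven by the per-layer edge-infection probabilities `v_i`. Because
$\dot w_i = \gamma v_i$ (with `w_i` the removed fraction at the far end of a
random layer-`i` edge) and `s_k(t) = s_k(0)\prod_i u_i^{k_i}` with
$u_i = e^{-\beta_i w_i/\gamma}$, the whole hierarchy collapses — exactly,
given $w(0) = 0$ — to
$$\gamma^{-1}\dot w_i = 1 - w_i - \tilde H_i\!\big(e^{-\beta_1 w_1/\gamma},
  \dots, e^{-\beta_n w_n/\gamma}\big).$$
`integrate_reduced()` works in `w`-coordinates rather than `u`: the two are
equivalent, but the `u`-form carries a `log u` singularity at `u -> 0+` and
conditions poorly. `full_degree_system()` integrates the unreduced
degree-class system on the truncated joint-degree grid (capped at `1e5`
cells) purely as the independent check; the two agree to `1e-6` in the
tests.

**Equilibria.** Equilibria solve $w_i = 1 - \tilde H_i(u(w))$. The
right-hand side `g` is increasing in `w`, and `mf_equilibrium()` iterates
*downward from* `w = 1`, converging monotonically to the greatest fixed
point. This direction matters: when everyone starts susceptible
(`E[s(0)] = 1`), `w = 0` is itself a fixed point, so upward iteration from 0
can never leave the disease-free state, while the downward sweep reaches the
epidemic equilibrium above threshold and returns 0 below it. For one layer
`g` is increasing and concave, so the nonzero root is unique. Similarly,
`integrate_reduced()` seeds `w(0) = 1e-8` when `E[s(0)] = 1` (the
disease-free state is an exact equilibrium of the flow); pass `w0 = 0` to
keep the system there.

**Early growth.** Linearising about `w = 0` gives
$\dot w = \gamma(1 - \mathbf E[s(0)])\mathbf 1 + \gamma(\mathcal R^{\tilde H}
- I)w$ with $T_i = \beta_i/\gamma$, so each eigenmode evolves at rate
$\gamma(\lambda_l - 1)$: near-exponential early growth occurs exactly when
the spectral radius exceeds 1. `early_growth()` returns the mode rates and
the closed-form linearised solution (including the eigenvector geometry that
a scalar treatment of the mode sum would miss). Convergence of the
trajectories is proven by phase-plane arguments only for `n = 1, 2`; for
`n >= 3` the package monitors `max |dw/dt|` rather than assuming it.

## Stochastic oracles and the two transmissibility conventions

`sample_multilayer_graph()` realises an ensemble as a configuration-model
graph per layer (i.i.d. degrees, odd stub totals fixed by one redraw,
uniform stub matching with bounded retries, then erasure of self-loops and
duplicates with a warning — the deterministic models assume simple
adjacency). `bond_percolation()` opens layer-`i` edges independently with
probability `T_i`, exhaustively over all `2^E` states on tiny graphs
(≤ 20 edges) or by Monte Carlo; `gillespie_sir()` is an exact event-driven
simulation of the continuous-time SIR process.

One subtlety is deliberate and surfaced rather than hidden: the
deterministic models' natural per-edge transmissibility is
$T_i = \beta_i/\gamma$ (expected transmissions per edge over a mean
infectious period), while in the Markovian stochastic process a given edge
transmits with probability $\beta_i/(\beta_i + \gamma)$ (competing
exponentials). Naively giving both models the same rates therefore biases
any comparison. Cross-model validation uses
`match_transmissibility(T, gamma)` = $\gamma T/(1-T)$ so the stochastic
per-edge transmission probability equals the model's `T`.

**Study conditions for the stochastic comparison.** The mean-field vs
Gillespie check uses a two-layer Poisson ensemble with means (15, 10),
`T = (0.1, 0.05)`, `gamma = 1` — so $R_0 = T_1 N_1 + T_2 N_2 = 2$ — on a
10,000-vertex configuration graph, outbreak-conditioned (final size > 5% of
`N`) because the stochastic process can go extinct while the deterministic
system cannot. High mean degree with small per-edge transmissibility is
precisely the regime in which a degree-based mean-field closure is expected
to be accurate (many weak, roughly independent exposures); the test asserts
agreement within 5 percentage points. The 500-point Monte Carlo suites on
small graphs use 3-standard-error bands.

## What the synthetic generator does and does not emulate

The configuration model reproduces the target degree distributions and is
locally tree-like at scale, which is exactly the structural assumption of
both mean-field frameworks. It does *not* produce clustering, degree
correlations between layers, community structure, or repeated/weighted
contacts — all present in real contact data. Passing the validation suite
therefore demonstrates internal consistency of the models with their own
assumptions, not accuracy on networks that violate them; on clustered or
assortative networks the mean-field predictions can err substantially, and
two networks with identical degree distributions can behave differently in
ways these models cannot distinguish.

## Numerical choices, in one place

* **Truncation**: each layer pmf is cut at the smallest `K` with tail mass
  below `tail_tol` (default `1e-10`); joint supports are product-truncated.
  Power-law layers are normalised on a finite support `kmin..kmax`
  (truncated power law). Closed-form pgfs are used for regular, Poisson and
  geometric layers, truncated polynomials otherwise; the two routes are
  cross-checked in the tests.
* **Fixed points**: percolation from `q = 0` (least root), mean-field
  equilibrium from `w = 1` (greatest root), final size from `r = 1 - s0`;
  all monotone, all at sup-norm residual `1e-12` by default.
* **ODE tolerances**: `rtol 1e-8` / `atol 1e-10` (vertex model),
  `rtol 1e-10` / `atol 1e-12` (reduced model); `lsoda`/`lsodar` via deSolve.
* **Degenerate inputs**: zero-mean-degree layers, all-degree-0 ensembles,
  `Gtilde''(1) = 0` expansions, odd-regular degree sums on odd `N`, and
  over-budget exhaustive enumerations all fail fast with named errors.
* **Randomness**: every stochastic routine takes an explicit seed; fixed
  seed means identical graphs, event sequences and outputs.
* **Problem sizes** (chosen to keep the full validation suite near a
  minute): 10,000-vertex graphs for the mean-field comparisons, 20
  Gillespie replicates there, 4,000 Monte Carlo replicates on the
  12-vertex exhaustive-agreement graph.

## Limitations

Beyond the synthetic-generator caveats above: the vertex-level ODE already
closes pairs as products (`s_v x_w`), so even on the true graph it is an
approximation; no pair-approximation or moment-closure corrections are
provided. Directed networks, degree-correlated layers, demographic
turnover, SEIR-type latency, exact cluster-size distributions and site
percolation are out of scope. The late-stage model and the dynamic models
use different transmissibility semantics by design; the package converts
between them only when explicitly asked.
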