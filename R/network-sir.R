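#' Per-layer transmission rates and recovery rate
#'
#' Dynamic parameters of the network SIR models: each layer-`i` contact of an
#' infectious vertex transmits at rate `beta_i` per unit time, and infectious
#' vertices recover at rate `gamma`. The derived per-edge transmissibility of
#' the deterministic models is `T_i = beta_i / gamma` (the expected number of
#' transmissions along one edge over a mean infectious period); note this
#' differs from the per-edge transmission probability `beta_i / (beta_i +
#' gamma)` of the event-driven stochastic model, see [match_transmissibility()].
#'
#' @param beta Numeric vector of per-layer transmission rates (>= 0).
#' @param gamma Recovery rate (> 0).
#' @return Object of class `sir_params` with `beta`, `gamma` and derived `T`.
#' @export
sir_params <- function(beta, gamma) {
  if (!is.numeric(beta) || any(beta < 0)) {
    stop("`beta` must be a nonnegative numeric vector", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("`gamma` must be a single positive rate", call. = FALSE)
  }
  structure(list(beta = as.numeric(beta), gamma = gamma,
                 T = as.numeric(beta) / gamma),
            class = "sir_params")
}

#' Expected number of onward infections per vertex
#'
#' `R(v) = sum_i (beta_i / gamma) k_i(v)`: the mean number of infections a
#' vertex would cause if infected, given its per-layer degrees.
#'
#' @param g A [multilayer_graph()].
#' @param params [sir_params()].
#' @param v Optional vertex ids (0-based); defaults to all vertices.
#' @return Numeric vector of `R(v)`.
#' @export
expected_infections <- function(g, params, v = NULL) {
  stopifnot(inherits(g, "multilayer_graph"), inherits(params, "sir_params"))
  if (length(params$beta) != g$n) {
    stop("`beta` must have one rate per layer", call. = FALSE)
  }
  Rv <- as.numeric(params$T %*% g$degrees)
  if (is.null(v)) Rv else Rv[v + 1L]
}

#' Integrate the vertex-level multilayer SIR system
#'
#' Integrates, for every vertex `v`, the mean-field equations
#' \deqn{\dot s_v = - s_v \sum_i \beta_i \sum_w A^i_{vw} x_w, \quad
#'       \dot x_v = -\gamma x_v + s_v \sum_i \beta_i \sum_w A^i_{vw} x_w,}
#' with `r_v = 1 - s_v - x_v` eliminated by conservation (so the integrated
#' state has dimension `2N` and per-vertex compartment sums are conserved
#' exactly). Integration stops early once the total infected mass drops below
#' `x_total_min`. The quantity
#' `H(v) = s_v exp((1/gamma) sum_i beta_i sum_w A^i_vw r_w)` is a first
#' integral of the system; its maximal relative drift over the trajectory is
#' reported as an integrator diagnostic.
#'
#' @param g A [multilayer_graph()].
#' @param params [sir_params()].
#' @param init List with numeric `N`-vectors `s`, `x` (and optionally `r`),
#'   each in `[0, 1]` with `s + x + r <= 1`. Default: `x = 1e-5`, `r = 0`.
#' @param t_end Final time.
#' @param n_out Number of output time points.
#' @param rtol,atol Integrator tolerances (lsodar).
#' @param x_total_min Early-stop threshold on `sum(x)`.
#' @return Object of class `sir_trajectory`: list with `times`, matrices `s`,
#'   `x`, `r` (rows = times), and `diagnostics` (`max_sum_drift`,
#'   `max_H_drift`).
#' @export
integrate_sir <- function(g, params, init = NULL, t_end = 100, n_out = 201,
                          rtol = 1e-8, atol = 1e-10, x_total_min = 1e-10) {
  stopifnot(inherits(g, "multilayer_graph"), inherits(params, "sir_params"))
  N <- g$N
  if (is.null(init)) {
    init <- list(s = rep(1 - 1e-5, N), x = rep(1e-5, N), r = rep(0, N))
  }
  if (is.null(init$r)) init$r <- 1 - init$s - init$x
  with_vals <- c(init$s, init$x, init$r)
  if (any(with_vals < -1e-12 | with_vals > 1 + 1e-12) ||
      any(abs(init$s + init$x + init$r - 1) > 1e-9)) {
    stop("initial compartments must lie in [0, 1] and sum to 1 per vertex",
         call. = FALSE)
  }
  times <- seq(0, t_end, length.out = n_out)
  A <- g$adjacency
  beta <- params$beta
  gamma <- params$gamma

  if (sum(init$x) <= x_total_min) {
    # disease-free start: the state is constant
    s <- matrix(init$s, n_out, N, byrow = TRUE)
    x <- matrix(init$x, n_out, N, byrow = TRUE)
    r <- matrix(init$r, n_out, N, byrow = TRUE)
    return(new_sir_trajectory(times, s, x, r, g, params))
  }

  deriv <- function(t, y, parms) {
    s <- y[1:N]; x <- y[(N + 1):(2 * N)]
    force_inf <- numeric(N)
    for (i in seq_along(A)) {
      force_inf <- force_inf + beta[i] * as.numeric(A[[i]] %*% x)
    }
    ds <- -s * force_inf
    dx <- -ds - gamma * x
    list(c(ds, dx))
  }
  root <- function(t, y, parms) sum(y[(N + 1):(2 * N)]) - x_total_min

  sol <- deSolve::ode(y = c(init$s, init$x), times = times, func = deriv,
                      parms = NULL, method = "lsodar", rtol = rtol,
                      atol = atol, rootfunc = root)
  tt <- sol[, 1]
  s <- sol[, 1 + (1:N), drop = FALSE]
  x <- sol[, 1 + N + (1:N), drop = FALSE]
  # recover r from the initial offset: r(t) = r(0) + (1 - s - x) - (1 - s0 - x0)
  r <- sweep(1 - s - x, 2, 1 - init$s - init$x - init$r, "-")
  new_sir_trajectory(tt, s, x, r, g, params)
}

new_sir_trajectory <- function(times, s, x, r, g, params) {
  sum_drift <- max(abs(s + x + r - 1))
  # H(v, t) = s exp((1/gamma) sum_i beta_i A_i r): conserved along exact flows
  Hmat <- matrix(NA_real_, nrow(s), ncol(s))
  for (ti in seq_len(nrow(s))) {
    expo <- numeric(g$N)
    for (i in seq_len(g$n)) {
      expo <- expo + params$beta[i] * as.numeric(g$adjacency[[i]] %*% r[ti, ])
    }
    Hmat[ti, ] <- s[ti, ] * exp(expo / params$gamma)
  }
  H_drift <- max(abs(sweep(Hmat, 2, Hmat[1, ], "-")))
  structure(list(times = times, s = s, x = x, r = r,
                 diagnostics = list(max_sum_drift = sum_drift,
                                    max_H_drift = H_drift)),
            class = "sir_trajectory")
}

#' @export
print.sir_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("<sir_trajectory: %d time points on [0, %.4g], %d vertices>\n",
              nt, max(x$times), ncol(x$s)))
  cat(sprintf("  final means: s = %.6g, x = %.3g, r = %.6g\n",
              mean(x$s[nt, ]), mean(x$x[nt, ]), mean(x$r[nt, ])))
  cat(sprintf("  max compartment-sum drift %.3g, max H drift %.3g\n",
              x$diagnostics$max_sum_drift, x$diagnostics$max_H_drift))
  invisible(x)
}

#' Final epidemic size on an explicit graph
#'
#' Solves the per-vertex final-size fixed point
#' \deqn{r_v = 1 - s_v(0) \exp\left(-\sum_i \frac{\beta_i}{\gamma}
#'       \sum_w A^i_{vw} r_w\right)}
#' by monotone iteration from `r = 1 - s0` (the initially non-susceptible
#' mass), so that a seeded initial condition converges to the nontrivial
#' root. With `s0` identically 1 the start is the trivial root `r = 0`; use
#' `interior_eps > 0` to start from an interior point and select the epidemic
#' root instead. The result satisfies the bound of [final_size_bound()].
#'
#' @param g A [multilayer_graph()].
#' @param params [sir_params()].
#' @param s0 Initial susceptible fraction per vertex (scalar or `N`-vector).
#' @param tol Sup-norm residual tolerance.
#' @param max_iter Maximum iterations.
#' @param interior_eps Optional interior starting offset in `[0, 1)`.
#' @return Numeric `N`-vector `r(Inf)` with attributes `iterations` and
#'   `residual`.
#' @export
final_size <- function(g, params, s0 = 1, tol = 1e-12, max_iter = 100000,
                       interior_eps = 0) {
  stopifnot(inherits(g, "multilayer_graph"), inherits(params, "sir_params"))
  N <- g$N
  s0 <- rep_len(s0, N)
  if (any(s0 < 0 | s0 > 1)) stop("`s0` must lie in [0, 1]", call. = FALSE)
  A <- g$adjacency
  Tl <- params$T
  Fmap <- function(r) {
    expo <- numeric(N)
    for (i in seq_len(g$n)) {
      expo <- expo + Tl[i] * as.numeric(A[[i]] %*% r)
    }
    1 - s0 * exp(-expo)
  }
  r <- pmax(1 - s0, interior_eps)
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fr <- Fmap(r)
    res <- max(abs(fr - r))
    r <- fr
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf("final-size iteration did not converge in %d iterations (residual %.3g)",
                 max_iter, res), call. = FALSE)
  }
  structure(r, iterations = iter, residual = res)
}

#' Upper bound on the final size
#'
#' The per-vertex bound `r_v(Inf) <= 1 - s_v(0) exp(-R(v))`, increasing in
#' the expected onward infections `R(v)`.
#'
#' @inheritParams final_size
#' @return Numeric `N`-vector of bounds.
#' @export
final_size_bound <- function(g, params, s0 = 1) {
  stopifnot(inherits(g, "multilayer_graph"), inherits(params, "sir_params"))
  s0 <- rep_len(s0, g$N)
  1 - s0 * exp(-expected_infections(g, params))
}
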