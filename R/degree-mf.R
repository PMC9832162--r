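#' Integrate the reduced degree-based mean-field SIR system
#'
#' The degree-class SIR system (one compartment triple per joint degree)
#' reduces exactly, when no one starts removed (`w(0) = 0`), to `n` equations
#' for the per-layer removed-edge fractions `w_i` (the mean removed
#' probability of the vertex at the far end of a random layer-`i` edge):
#' \deqn{\gamma^{-1} \dot w_i = 1 - w_i -
#'       \tilde H_i(e^{-\beta_1 w_1/\gamma}, \ldots, e^{-\beta_n w_n/\gamma}).}
#' Susceptible classes are recovered in closed form as
#' `s_k(t) = s_k(0) prod_i u_i^{k_i}` with `u_i = exp(-beta_i w_i / gamma)`.
#' The system is integrated in `w`-coordinates (rather than `u`) to avoid the
#' logarithmic singularity at `u -> 0`.
#'
#' When everyone starts susceptible (`E[s(0)] = 1`) the disease-free state
#' `w = 0` is an exact equilibrium, so the integration is seeded with an
#' infinitesimal `w0` (default `1e-8`), mirroring the infinitesimal infected
#' seed of the vertex-level model; pass `w0 = 0` to keep the system at the
#' disease-free state.
#'
#' @param e A [network_ensemble()] (its `T` slot is ignored here; rates come
#'   from `params`).
#' @param params [sir_params()] with one `beta` per layer.
#' @param s0 Initial susceptibility (constant or [initial_susceptibility()]).
#' @param t_end Final time.
#' @param n_out Number of output times.
#' @param rtol,atol Integrator tolerances.
#' @param w0 Initial `w` (scalar or `n`-vector); `NULL` picks `1e-8` when
#'   `E[s(0)] = 1` and `0` otherwise.
#' @param reconstruct If `TRUE`, also reconstruct per-joint-degree
#'   compartments `s_k, x_k, r_k` on the truncated degree grid (capped at
#'   `grid_cap` cells).
#' @param grid_cap Maximum number of joint-degree cells for reconstruction.
#' @return Object of class `degree_mf_trajectory`: list with `times` and
#'   matrices `w`, `u`, `v` (`n` columns), aggregate `s`, `x`, `r` vectors,
#'   and (optionally) `classes` (list with `support`, `s`, `x`, `r`).
#' @export
integrate_reduced <- function(e, params, s0 = 1, t_end = 50, n_out = 201,
                              rtol = 1e-10, atol = 1e-12, w0 = NULL,
                              reconstruct = FALSE, grid_cap = 1e5) {
  stopifnot(inherits(e, "network_ensemble"), inherits(params, "sir_params"))
  if (length(params$beta) != e$n) {
    stop("`beta` must have one rate per layer", call. = FALSE)
  }
  s0 <- as_s0(s0)
  n <- e$n
  beta <- params$beta
  gamma <- params$gamma
  Es0 <- mean_s0(e, s0)
  if (Es0 > 1 + 1e-12) stop("E[s(0)] must be <= 1", call. = FALSE)
  if (is.null(w0)) w0 <- if (abs(Es0 - 1) < 1e-14) 1e-8 else 0
  w0 <- rep_len(w0, n)

  Hvec <- function(u) {
    vapply(seq_len(n), function(i) gf_H_layer(e, i, u, s0 = s0), numeric(1))
  }
  grid <- NULL
  if (reconstruct) {
    grid <- joint_pmf(e)
    if (length(grid$prob) > grid_cap) {
      stop(sprintf(
        "joint-degree grid has %d cells (cap %g); raise `grid_cap` or use the reduced system without reconstruction",
        length(grid$prob), grid_cap), call. = FALSE)
    }
    sk0 <- s0_lookup(s0, grid$support)
  }

  # state: (w_1..w_n, aggregate r, [class r_k ...])
  nclass <- if (reconstruct) length(grid$prob) else 0
  deriv <- function(t, y, parms) {
    w <- pmin(pmax(y[1:n], 0), 1)
    r_agg <- y[n + 1]
    u <- exp(-beta / gamma * w)
    dw <- gamma * (1 - w - Hvec(u))
    s_agg <- agg_s(e, s0, u, grid)
    dr <- gamma * (1 - s_agg - r_agg)
    if (!nclass) return(list(c(dw, dr)))
    rk <- y[n + 1 + seq_len(nclass)]
    sk <- sk0 * apply_u_powers(grid$support, u)
    drk <- gamma * (1 - sk - rk)
    list(c(dw, dr, drk))
  }
  y0 <- c(w0, 0, if (nclass) rep(0, nclass))
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  tt <- sol[, 1]
  w <- sol[, 1 + (1:n), drop = FALSE]
  dimnames(w) <- NULL
  r_agg <- unname(sol[, n + 2])
  u <- exp(sweep(-w, 2, beta / gamma, "*"))
  H <- t(apply(u, 1, Hvec))
  if (n == 1) H <- matrix(H, ncol = 1)
  v <- 1 - w - H
  s_agg <- vapply(seq_len(nrow(u)),
                  function(ti) agg_s(e, s0, u[ti, ], grid), numeric(1))
  x_agg <- 1 - s_agg - r_agg
  classes <- NULL
  if (nclass) {
    rk <- sol[, n + 2 + seq_len(nclass), drop = FALSE]
    dimnames(rk) <- NULL
    sk <- vapply(seq_len(nrow(u)),
                 function(ti) sk0 * apply_u_powers(grid$support, u[ti, ]),
                 numeric(nclass))
    sk <- matrix(t(sk), nrow = nrow(u), ncol = nclass)
    classes <- list(support = grid$support, prob = grid$prob,
                    s = sk, r = rk, x = 1 - sk - rk)
  }
  structure(list(times = tt, w = w, u = u, v = v,
                 s = s_agg, x = x_agg, r = r_agg, classes = classes,
                 params = params, Es0 = Es0),
            class = "degree_mf_trajectory")
}

# aggregate susceptible fraction E[s_k(0) prod u^k]
agg_s <- function(e, s0, u, grid = NULL) {
  if (s0$mode == "constant") return(s0$s0 * gf_joint(e, u))
  if (is.null(grid)) grid <- joint_pmf(e)
  sum(grid$prob * s0_lookup(s0, grid$support) *
        apply_u_powers(grid$support, u))
}

apply_u_powers <- function(support, u) {
  out <- rep(1, nrow(support))
  for (j in seq_len(ncol(support))) out <- out * u[j]^support[, j]
  out
}

#' @export
print.degree_mf_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("<degree_mf_trajectory: %d layers, %d times on [0, %.4g]>\n",
              ncol(x$w), nt, max(x$times)))
  cat("  w(final):", paste(signif(x$w[nt, ], 6), collapse = ", "), "\n")
  cat(sprintf("  aggregate final: s = %.6g, x = %.3g, r = %.6g\n",
              x$s[nt], x$x[nt], x$r[nt]))
  invisible(x)
}

#' Equilibrium of the degree-based mean-field system
#'
#' Solves the fixed-point system
#' `w_i = 1 - Htilde_i(exp(-beta_1 w_1 / gamma), ..., exp(-beta_n w_n /
#' gamma))` by monotone iteration downward from `w = 1`, which converges to
#' the greatest fixed point: the epidemic equilibrium when one exists, and
#' `w = 0` below threshold when `E[s(0)] = 1`. (Iterating up from `w = 0` is
#' unusable when everyone starts susceptible, because `w = 0` is then itself
#' a fixed point.) For a single layer the fixed-point function is increasing
#' and concave, so the nonzero root is unique. Per-degree equilibrium
#' susceptibilities follow as
#' `s_k_eq = s_k(0) exp(-sum_i beta_i k_i w_i_eq / gamma)`.
#'
#' @inheritParams integrate_reduced
#' @param tol Sup-norm residual tolerance.
#' @param max_iter Maximum iterations.
#' @return List with `w` (equilibrium vector), `u`, `residual`, `iterations`,
#'   `final_size` (aggregate `1 - E[s_k(0) prod u^k]`) and `s_eq`, a function
#'   mapping a joint degree vector to its equilibrium susceptibility.
#' @examples
#' e <- network_ensemble(degree_distribution("regular", k = 4),
#'                       transmissibility = 0.5)
#' mf_equilibrium(e, sir_params(0.5, 1))$w   # root of w = 1 - exp(-2 w)
#' @export
mf_equilibrium <- function(e, params, s0 = 1, tol = 1e-12, max_iter = 100000) {
  stopifnot(inherits(e, "network_ensemble"), inherits(params, "sir_params"))
  s0 <- as_s0(s0)
  n <- e$n
  beta <- params$beta
  gamma <- params$gamma
  g <- function(w) {
    u <- exp(-beta / gamma * w)
    vapply(seq_len(n), function(i) 1 - gf_H_layer(e, i, u, s0 = s0),
           numeric(1))
  }
  w <- rep(1, n)
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gw <- g(w)
    res <- max(abs(gw - w))
    w <- pmin(pmax(gw, 0), 1)
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf("equilibrium iteration did not converge in %d iterations (residual %.3g)",
                 max_iter, res), call. = FALSE)
  }
  u <- exp(-beta / gamma * w)
  s_eq <- function(k) {
    stopifnot(length(k) == n)
    kmat <- matrix(as.integer(k), 1)
    colnames(kmat) <- paste0("k", seq_len(n))
    s0_lookup(s0, kmat) * prod(u^k)
  }
  list(w = w, u = u, residual = res, iterations = iter,
       final_size = 1 - agg_s(e, s0, u), s_eq = s_eq)
}

#' Early-growth analysis of the reduced mean-field system
#'
#' Linearising the reduced system about `w = 0` gives
#' `dw/dt = gamma (1 - E[s(0)]) 1 + gamma (R - I) w`, where `R` is the
#' `Htilde` reproduction matrix with transmissibilities `T_i = beta_i /
#' gamma`. Each eigenmode grows or decays at rate `gamma (lambda_l - 1)`, so
#' early near-exponential growth of an outbreak occurs exactly when the
#' spectral radius exceeds 1.
#'
#' @inheritParams integrate_reduced
#' @return List with `lambda` (eigenvalues of the `Htilde` R-matrix), `rates`
#'   (`gamma (lambda - 1)`), `outbreak_growth` (`max(lambda) > 1`),
#'   `r_matrix`, and `w_lin(t, w0 = 0)`: the closed-form linearised solution
#'   (matrix with one row per `t`).
#' @export
early_growth <- function(e, params, s0 = 1) {
  stopifnot(inherits(e, "network_ensemble"), inherits(params, "sir_params"))
  s0 <- as_s0(s0)
  n <- e$n
  gamma <- params$gamma
  # Htilde R-matrix with T_i = beta_i / gamma (which may exceed 1)
  eT <- e
  eT$T <- params$T
  R <- r_matrix(eT, "Htilde", s0 = s0)
  ev <- eigen(R$entries)
  if (abs(det(ev$vectors)) < 1e-12) {
    stop(sprintf("Htilde R-matrix is not diagonalisable; eigenvalues: %s",
                 paste(signif(ev$values, 8), collapse = ", ")), call. = FALSE)
  }
  lambda <- ev$values
  if (max(abs(Im(lambda))) < 1e-12) lambda <- Re(lambda)
  V <- ev$vectors
  Es0 <- mean_s0(e, s0)
  cpart <- solve(V, rep(gamma * (1 - Es0), n))   # forcing in eigencoordinates
  rates <- gamma * (lambda - 1)
  w_lin <- function(t, w0 = 0) {
    w0 <- rep_len(w0, n)
    b <- solve(V, w0)
    out <- vapply(t, function(tt) {
      mode_vals <- vapply(seq_len(n), function(l) {
        lam <- rates[l]
        if (abs(lam) < 1e-14) {
          b[l] + cpart[l] * tt
        } else {
          b[l] * exp(lam * tt) + cpart[l] / lam * (exp(lam * tt) - 1)
        }
      }, complex(1))
      Re(V %*% mode_vals)
    }, numeric(n))
    t(matrix(out, nrow = n))
  }
  list(lambda = lambda, rates = Re(rates),
       outbreak_growth = max(Re(lambda)) > 1,
       r_matrix = R, w_lin = w_lin)
}

#' Integrate the full degree-class SIR system
#'
#' Integrates the unreduced system directly on the truncated joint-degree
#' grid: for each class `k`,
#' `ds_k/dt = -sum_i beta_i k_i v_i s_k`,
#' `dx_k/dt = -gamma x_k + sum_i beta_i k_i v_i s_k`,
#' with `v_i = sum_k Ptilde_i(k) x_(k + e_i)` the probability that the far
#' end of a random layer-`i` edge is infected. Used as the independent check
#' that the `n`-dimensional reduction of [integrate_reduced()] is exact.
#'
#' @inheritParams integrate_reduced
#' @param grid_cap Maximum number of joint-degree cells.
#' @return Object of class `degree_full_trajectory`: list with `times`,
#'   `support`, `prob`, matrices `s`, `x`, `r` (rows = times, columns =
#'   classes), `v`, and aggregates `s_agg`, `x_agg`, `r_agg`.
#' @export
full_degree_system <- function(e, params, s0 = 1, t_end = 50, n_out = 201,
                               rtol = 1e-10, atol = 1e-12, grid_cap = 1e5) {
  stopifnot(inherits(e, "network_ensemble"), inherits(params, "sir_params"))
  s0 <- as_s0(s0)
  n <- e$n
  beta <- params$beta
  gamma <- params$gamma
  grid <- joint_pmf(e)
  m <- length(grid$prob)
  if (m > grid_cap) {
    stop(sprintf(
      "joint-degree grid has %d cells (cap %g); use integrate_reduced() instead",
      m, grid_cap), call. = FALSE)
  }
  sup <- grid$support
  key <- apply(sup, 1, paste, collapse = ",")
  # per layer: excess pmf weights and the grid cell holding x_{k + e_i}
  vmaps <- lapply(seq_len(n), function(i) {
    ep <- layer_excess_pmf(e, i)
    kplus <- ep$support
    kplus[, i] <- kplus[, i] + 1L
    idx <- match(apply(kplus, 1, paste, collapse = ","), key)
    keep <- !is.na(idx)
    list(weight = ep$prob[keep], idx = idx[keep])
  })
  sk0 <- s0_lookup(s0, sup)
  x0 <- 1 - sk0
  deriv <- function(t, y, parms) {
    s <- y[1:m]; x <- y[m + (1:m)]
    v <- vapply(seq_len(n), function(i) {
      sum(vmaps[[i]]$weight * x[vmaps[[i]]$idx])
    }, numeric(1))
    lam <- as.numeric(sup %*% (beta * v))   # sum_i beta_i k_i v_i per class
    ds <- -lam * s
    dx <- -gamma * x + lam * s
    list(c(ds, dx))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = c(sk0, x0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  s <- sol[, 1 + (1:m), drop = FALSE]
  x <- sol[, 1 + m + (1:m), drop = FALSE]
  r <- 1 - s - x
  v <- t(vapply(seq_len(nrow(s)), function(ti) {
    vapply(seq_len(n), function(i) {
      sum(vmaps[[i]]$weight * x[ti, vmaps[[i]]$idx])
    }, numeric(1))
  }, numeric(n)))
  structure(list(times = sol[, 1], support = sup, prob = grid$prob,
                 s = s, x = x, r = r, v = v,
                 s_agg = as.numeric(s %*% grid$prob),
                 x_agg = as.numeric(x %*% grid$prob),
                 r_agg = as.numeric(r %*% grid$prob)),
            class = "degree_full_trajectory")
}
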