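#' Late-stage outbreak: per-layer escape probabilities
#'
#' Solves the n-dimensional fixed-point system
#' `q_i = 1 - T_i + T_i * Gtilde_i(q_1, ..., q_n)`,
#' where `q_i` is the probability that a given layer-`i` edge never transmits
#' the infection to the vertex under consideration. The map is monotone
#' nondecreasing and maps `[0,1]^n` into itself, so iterating from `q = 0`
#' produces a nondecreasing sequence converging to the least fixed point:
#' below the epidemic threshold that point is `(1, ..., 1)` (no outbreak);
#' above it every `q_i < 1` and the overall escape probability
#' `P = G(q)` is less than 1.
#'
#' @param e A [network_ensemble()].
#' @param tol Convergence tolerance on the sup-norm residual (`<= 1e-6`).
#' @param max_iter Maximum number of fixed-point iterations.
#' @param damping Relaxation factor `alpha` in `q <- (1 - alpha) q +
#'   alpha F(q)`; reduced to 0.5 automatically if oscillation is detected.
#' @return An object of class `percolation_solution`: list with `q`,
#'   `epsilon` (where `q_i = 1 - T_i epsilon_i`), `escape_probability`
#'   (`P = G(q)`), `outbreak` (`TRUE` when `q != 1`), `converged`,
#'   `iterations`, `residual`.
#' @examples
#' e <- network_ensemble(degree_distribution("regular", k = 3),
#'                       transmissibility = 0.75)
#' solve_percolation(e)$q   # (1 - T)/T = 1/3
#' @export
solve_percolation <- function(e, tol = 1e-12, max_iter = 200000,
                              damping = 1) {
  stopifnot(inherits(e, "network_ensemble"))
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-6) {
    stop("`tol` must lie in (0, 1e-6]", call. = FALSE)
  }
  n <- e$n
  Fmap <- function(q) {
    vapply(seq_len(n),
           function(i) 1 - e$T[i] + e$T[i] * gf_excess_layer(e, i, q),
           numeric(1))
  }
  q <- rep(0, n)
  alpha <- damping
  res <- Inf
  iter <- 0L
  prev_step <- rep(0, n)
  while (iter < max_iter) {
    iter <- iter + 1L
    fq <- Fmap(q)
    res <- max(abs(fq - q))
    if (res < tol) {
      q <- fq
      break
    }
    step <- fq - q
    # oscillation: successive steps pointing in opposite directions
    if (alpha == 1 && iter > 1 && sum(step * prev_step) < 0) alpha <- 0.5
    prev_step <- step
    q <- pmin(pmax((1 - alpha) * q + alpha * fq, 0), 1)
  }
  converged <- res < tol
  if (!converged) {
    stop(sprintf(
      "percolation fixed point did not converge in %d iterations (residual %.3g); last iterate: %s",
      max_iter, res, paste(signif(q, 8), collapse = ", ")), call. = FALSE)
  }
  eps <- ifelse(e$T > 0, (1 - q) / e$T, 0)
  structure(
    list(q = q, epsilon = eps,
         escape_probability = gf_joint(e, q),
         outbreak = max(abs(q - 1)) > 1e-8,
         converged = converged, iterations = iter, residual = res),
    class = "percolation_solution"
  )
}

#' @export
print.percolation_solution <- function(x, ...) {
  cat("<percolation_solution>\n")
  cat("  q        :", paste(signif(x$q, 8), collapse = ", "), "\n")
  cat(sprintf("  P = G(q) : %.8g\n", x$escape_probability))
  cat(sprintf("  outbreak : %s (%d iterations, residual %.3g)\n",
              x$outbreak, x$iterations, x$residual))
  invisible(x)
}

#' Escape probability of a random or given vertex
#'
#' With the fixed-point vector `q` from [solve_percolation()], a vertex with
#' joint degree `(k_1, ..., k_n)` escapes infection with probability
#' `prod_i q_i^{k_i}`; averaging over the joint degree pmf gives the overall
#' escape probability `P = G(q)`.
#'
#' @param e A [network_ensemble()].
#' @param q Numeric `n`-vector in `[0, 1]^n`.
#' @param degree Optional integer `n`-vector: return the per-degree escape
#'   probability for this joint degree instead of the average.
#' @return A single probability.
#' @export
escape_probability <- function(e, q, degree = NULL) {
  check_point(e, q)
  if (is.null(degree)) return(gf_joint(e, q))
  stopifnot(length(degree) == e$n, all(degree >= 0))
  prod(q^degree)
}

#' Sufficient condition for a late-stage outbreak
#'
#' Checks whether every per-layer reproduction number `R0(i)` exceeds 1, a
#' sufficient condition for the fixed-point system to have a nontrivial
#' solution in `(0, 1)^n` (so that a positive fraction of vertices is
#' eventually infected).
#'
#' @param e A [network_ensemble()].
#' @return List with `sufficient` (flag) and `r0_layers` (vector of `R0(i)`).
#' @export
outbreak_condition <- function(e) {
  stopifnot(inherits(e, "network_ensemble"))
  r0i <- vapply(seq_len(e$n), function(i) r0_layer(e, i), numeric(1))
  list(sufficient = all(r0i > 1), r0_layers = r0i)
}

#' Locate a percolation phase transition along a parameter path
#'
#' Evaluates the spectral radius `lambda(t)` of the `Gtilde` reproduction
#' matrix along a one-parameter family of ensembles and locates the crossing
#' `lambda(t*) = 1`, which marks the phase transition out of the no-outbreak
#' state. The crossing is bracketed on the grid and refined by bisection.
#'
#' @param e_of_t Function mapping a scalar `t` to a [network_ensemble()];
#'   must be continuous in `t`.
#' @param t_grid Sorted numeric grid of path parameters.
#' @param bracket_tol Bisection stops when the bracket is narrower than this.
#' @param cross_check If `TRUE`, verify with [solve_percolation()] that the
#'   least fixed point is all-ones just below `t*` and nontrivial just above.
#' @return An object of class `transition_scan`: list with `t_grid`,
#'   `lambda` (spectral radius on the grid), `t_star` (crossing, or `NA` if
#'   none bracketed), `bracket_width`, and `cross_check` results (if run).
#' @examples
#' path <- function(t) network_ensemble(
#'   degree_distribution("regular", k = 3), transmissibility = t)
#' scan_transition(path, seq(0.05, 0.95, by = 0.05))$t_star  # 0.5
#' @export
scan_transition <- function(e_of_t, t_grid, bracket_tol = 1e-6,
                            cross_check = FALSE) {
  stopifnot(is.function(e_of_t), !is.unsorted(t_grid))
  lam <- function(t) r_matrix(e_of_t(t), "Gtilde")$leading_eigenvalue
  lambda <- vapply(t_grid, lam, numeric(1))
  sgn <- sign(lambda - 1)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0 |
                   (sgn[-length(sgn)] == 0))[1]
  if (is.na(cross)) {
    return(structure(list(t_grid = t_grid, lambda = lambda, t_star = NA_real_,
                          bracket_width = NA_real_, cross_check = NULL),
                     class = "transition_scan"))
  }
  lo <- t_grid[cross]; hi <- t_grid[cross + 1]
  flo <- lambda[cross] - 1
  while (hi - lo > bracket_tol) {
    mid <- (lo + hi) / 2
    fmid <- lam(mid) - 1
    if (sign(fmid) == sign(flo) || fmid == 0 && flo == 0) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid
    }
  }
  t_star <- (lo + hi) / 2
  chk <- NULL
  if (cross_check) {
    off <- max(10 * bracket_tol, 1e-4 * (max(t_grid) - min(t_grid)))
    below <- solve_percolation(e_of_t(t_star - off))
    above <- solve_percolation(e_of_t(t_star + off))
    chk <- list(q_below = below$q, q_above = above$q,
                ok = !below$outbreak && above$outbreak)
  }
  structure(list(t_grid = t_grid, lambda = lambda, t_star = t_star,
                 bracket_width = hi - lo, cross_check = chk),
            class = "transition_scan")
}

#' @export
print.transition_scan <- function(x, ...) {
  cat("<transition_scan>\n")
  if (is.na(x$t_star)) {
    cat("  no unit-eigenvalue crossing bracketed on the grid\n")
  } else {
    cat(sprintf("  t* = %.8g (bracket width %.3g)\n",
                x$t_star, x$bracket_width))
  }
  invisible(x)
}

#' Near-critical expansion of the escape probability (single layer)
#'
#' Just above the threshold `Tc = 1/Gtilde'(1)` of a single-layer network, the
#' escape probability follows the linear law `1 - P ~ c (T - Tc)` with
#' `c = 2 G'(1) / (Gtilde''(1) Tc^2)`, i.e. the transition is a power law
#' with exponent 1. Returns the coefficient `c`. Degenerate when
#' `Gtilde''(1) = 0` (e.g. every vertex of degree 2).
#'
#' @param e A single-layer [network_ensemble()].
#' @return List with `coefficient` (`c`), `Tc`.
#' @examples
#' e <- network_ensemble(degree_distribution("regular", k = 3),
#'                       transmissibility = 0.6)
#' near_critical_slope(e)$coefficient   # 12
#' @export
near_critical_slope <- function(e) {
  stopifnot(inherits(e, "network_ensemble"))
  if (e$n != 1) {
    stop("the near-critical expansion is implemented for single-layer ensembles only",
         call. = FALSE)
  }
  d <- e$layers[[1]]
  gp1 <- pgf(d, 1, 1)                       # G'(1) = E(k)
  # Gtilde(x) = G'(x)/G'(1): derivatives from G'' and G'''-free identities
  gt1 <- pgf(d, 1, 2) / gp1                 # Gtilde'(1) = G''(1)/G'(1)
  if (gt1 <= 0) stop("degenerate layer: Gtilde'(1) = 0", call. = FALSE)
  Tc <- 1 / gt1
  # Gtilde''(1) = G'''(1)/G'(1) = E[k(k-1)(k-2)]/E(k): third factorial moment
  gt2 <- sum(d$degrees * (d$degrees - 1) * (d$degrees - 2) * d$pmf) / gp1
  if (gt2 <= 1e-14) {
    stop("degenerate expansion: Gtilde''(1) = 0 (linear excess pgf)",
         call. = FALSE)
  }
  list(coefficient = 2 * gp1 / (gt2 * Tc^2), Tc = Tc)
}
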