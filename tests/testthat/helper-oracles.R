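# shared fixtures and independent oracles, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# single 3-regular layer (explicit phase transition at T = 1/2)
ens_regular3 <- function(T = 0.75) {
  network_ensemble(degree_distribution("regular", k = 3),
                   transmissibility = T)
}

# two 2-regular layers (4 contacts per vertex in total)
ens_two_regular2 <- function(T1 = 0.25, T2 = 0.5) {
  network_ensemble(degree_distribution("regular", k = 2),
                   degree_distribution("regular", k = 2),
                   transmissibility = c(T1, T2))
}

# two Poisson layers
ens_two_poisson <- function(N1, N2, T1, T2, tail_tol = 1e-10) {
  network_ensemble(degree_distribution("poisson", mean = N1,
                                       tail_tol = tail_tol),
                   degree_distribution("poisson", mean = N2,
                                       tail_tol = tail_tol),
                   transmissibility = c(T1, T2))
}

# central finite-difference gradient of a scalar function on [0,1]^n
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- min(x[j] + h, 1)
    xm[j] <- max(x[j] - h, 0)
    (f(xp) - f(xm)) / (xp[j] - xm[j])
  }, numeric(1))
}

# mean of a joint pmf along each margin
joint_pmf_mean <- function(jp) {
  as.numeric(crossprod(jp$support, jp$prob))
}

# marginal pmf of layer j from a joint pmf
joint_pmf_marginal <- function(jp, j) {
  tapply(jp$prob, jp$support[, j], sum)
}

# high-precision damped iteration of the escape-probability fixed point,
# independent of solve_percolation's loop (uses the pgf definitions directly)
oracle_fixed_point <- function(e, n_iter = 100000) {
  q <- rep(0.5, e$n)
  for (it in seq_len(n_iter)) {
    fq <- vapply(seq_len(e$n), function(i) {
      1 - e$T[i] + e$T[i] * gf_excess_layer(e, i, q)
    }, numeric(1))
    q <- 0.5 * q + 0.5 * fq
  }
  q
}

# the printed quartic in q2 for two 2-regular layers
example5_quartic <- function(q2, T1, T2) {
  T1^2 * q2^4 + T1^2 * T2 * q2^3 + (T2 * T1 - 2) * T1 * q2^2 +
    T1 * T2 * (T1 - 2) * q2 - T2 + 1
}

# tiny deterministic multilayer graphs
graph_path3 <- function() {
  multilayer_graph(data.frame(layer = 1, u = c(0, 1), v = c(1, 2)))
}

graph_two_layer_toy <- function() {
  # 5 vertices; layer 1: path 0-1-2-3; layer 2: star around 4
  multilayer_graph(data.frame(
    layer = c(1, 1, 1, 2, 2, 2),
    u = c(0, 1, 2, 4, 4, 4),
    v = c(1, 2, 3, 0, 2, 3)))
}
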