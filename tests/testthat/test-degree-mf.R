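test_that("mean-field equilibrium matches scalar root-finding oracles", {
  # regular degree k with beta k / gamma = 2 and everyone susceptible:
  # w solves w = 1 - exp(-2 w); oracle by uniroot
  oracle <- uniroot(function(w) w - (1 - exp(-2 * w)),
                    c(1e-6, 1), tol = 1e-14)$root
  e4 <- network_ensemble(degree_distribution("regular", k = 4),
                         transmissibility = 0.5)
  eq <- mf_equilibrium(e4, sir_params(0.5, 1), s0 = 1)
  expect_equal(eq$w, oracle, tolerance = 1e-10)
  expect_equal(eq$w, 0.7968, tolerance = 1e-4)
  expect_lt(eq$residual, 1e-12)

  # below threshold with s0 = 1 the equilibrium is disease-free
  eq0 <- mf_equilibrium(e4, sir_params(0.2, 1), s0 = 1)  # T k = 0.8 < 1
  expect_equal(eq0$w, 0, tolerance = 1e-10)
  expect_equal(eq0$final_size, 0, tolerance = 1e-9)

  # E[s(0)] < 1: interior equilibrium with g(0) = 1 - E[s(0)] > 0
  e3 <- ens_regular3(T = 0.1)
  eqs <- mf_equilibrium(e3, sir_params(0.1, 1), s0 = 0.99)
  expect_gt(eqs$w, 0)
  expect_lt(eqs$w, 1)
  g0 <- 1 - gf_H_layer(e3, 1, 1, s0 = 0.99)
  expect_equal(g0, 1 - 0.99, tolerance = 1e-12)
  # per-degree equilibrium susceptibility from the closed form
  expect_equal(eqs$s_eq(3), 0.99 * exp(-0.1 * 3 * eqs$w), tolerance = 1e-10)
})

test_that("reduced trajectories converge to the equilibrium and stay ordered", {
  e <- ens_two_poisson(4, 2, 0.4, 0.3)
  p <- sir_params(c(0.4, 0.3), 1)
  tr <- integrate_reduced(e, p, s0 = 0.995, t_end = 120)
  eq <- mf_equilibrium(e, p, s0 = 0.995)
  nt <- length(tr$times)
  expect_equal(tr$w[nt, ], eq$w, tolerance = 1e-4)
  # w nondecreasing in [0,1]; u nonincreasing in (0,1]
  expect_true(all(diff(tr$w) > -1e-9))
  expect_true(all(tr$w >= -1e-12 & tr$w <= 1 + 1e-12))
  expect_true(all(diff(tr$u) < 1e-9))
  expect_true(all(tr$u > 0 & tr$u <= 1))
  # dw/dt = gamma v with v >= 0
  expect_true(all(tr$v > -1e-8))
  # below threshold with everyone susceptible, w stays at the seed scale
  e_cold <- network_ensemble(degree_distribution("regular", k = 4),
                             transmissibility = 0.2)
  tr_cold <- integrate_reduced(e_cold, sir_params(0.2, 1), s0 = 1, t_end = 50)
  expect_lt(max(tr_cold$w), 1e-6)
})

test_that("the n-equation reduction agrees with the full degree-class system", {
  e <- network_ensemble(degree_distribution("poisson", mean = 2),
                        degree_distribution("regular", k = 2),
                        transmissibility = c(0.5, 0.5))
  p <- sir_params(c(0.6, 0.4), 1)
  full <- full_degree_system(e, p, s0 = 0.99, t_end = 30)
  red <- integrate_reduced(e, p, s0 = 0.99, t_end = 30, reconstruct = TRUE)
  expect_lt(max(abs(full$s - red$classes$s)), 1e-6)
  expect_lt(max(abs(full$x - red$classes$x)), 1e-6)
  expect_lt(max(abs(full$r - red$classes$r)), 1e-6)
  # class compartments sum to one
  expect_lt(max(abs(red$classes$s + red$classes$x + red$classes$r - 1)),
            1e-9)

  # single degree class: identical to the reduced system
  e1 <- network_ensemble(degree_distribution("regular", k = 3),
                         transmissibility = 0.5)
  p1 <- sir_params(0.5, 1)
  full1 <- full_degree_system(e1, p1, s0 = 0.98, t_end = 25)
  red1 <- integrate_reduced(e1, p1, s0 = 0.98, t_end = 25, reconstruct = TRUE)
  expect_lt(max(abs(full1$s - red1$classes$s)), 1e-8)

  # beta = 0: susceptible classes are constant
  full0 <- full_degree_system(e1, sir_params(0, 1), s0 = 0.9, t_end = 10)
  expect_equal(max(abs(sweep(full0$s, 2, full0$s[1, ], "-"))), 0,
               tolerance = 1e-10)
})

test_that("early growth rates come from the Htilde reproduction matrix", {
  # single regular layer: R^Htilde = T k, rate beta k - gamma
  e4 <- network_ensemble(degree_distribution("regular", k = 4),
                         transmissibility = 0.5)
  eg <- early_growth(e4, sir_params(0.5, 1), s0 = 1)
  expect_equal(eg$lambda, 2, tolerance = 1e-12)
  expect_equal(eg$rates, 0.5 * 4 - 1, tolerance = 1e-12)
  expect_true(eg$outbreak_growth)

  # all modes subcritical with E[s(0)] = 1: linearised w stays at zero
  e_cold <- network_ensemble(degree_distribution("regular", k = 4),
                             transmissibility = 0.2)
  egc <- early_growth(e_cold, sir_params(0.2, 1), s0 = 1)
  expect_false(egc$outbreak_growth)
  expect_equal(egc$w_lin(c(1, 5, 10)), matrix(0, 3, 1))

  # nonlinear early slope matches gamma (lambda_max - 1) within 5%
  e6 <- ens_two_poisson(50, 2, 0.1, 0.6)
  p6 <- sir_params(c(0.1, 0.6), 1)
  eg6 <- early_growth(e6, p6, s0 = 1)
  rate <- max(eg6$rates)
  v_lead <- leading_eigen(eg6$r_matrix)$vector
  w0 <- 1e-9 * v_lead
  t_doubling <- log(2) / rate
  tr <- integrate_reduced(e6, p6, s0 = 1, w0 = w0,
                          t_end = t_doubling, n_out = 11,
                          rtol = 1e-12, atol = 1e-16)
  wn <- rowSums(tr$w)
  emp_rate <- (log(wn[11]) - log(wn[1])) / (tr$times[11] - tr$times[1])
  expect_equal(emp_rate, rate, tolerance = 0.05)

  # linearised solution with forcing matches the nonlinear system early on
  tr2 <- integrate_reduced(e6, p6, s0 = 0.9999, t_end = 0.05, n_out = 6,
                           w0 = 0, rtol = 1e-12, atol = 1e-16)
  lin <- early_growth(e6, p6, s0 = 0.9999)$w_lin(tr2$times)
  expect_equal(lin[6, ], tr2$w[6, ], tolerance = 1e-3)
})
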