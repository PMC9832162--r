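test_that("fixed-point solver reproduces the solvable single-layer cases", {
  # 2-regular: q = 1 for any T < 1
  for (T in c(0.3, 0.7, 0.99)) {
    e2 <- network_ensemble(degree_distribution("regular", k = 2),
                           transmissibility = T)
    sol <- solve_percolation(e2)
    expect_equal(sol$q, 1, tolerance = 1e-10)
    expect_false(sol$outbreak)
  }
  # 3-regular: q = (1 - T)/T above T = 1/2, else 1
  e3 <- ens_regular3(T = 0.75)
  sol3 <- solve_percolation(e3)
  expect_equal(sol3$q, 1 / 3, tolerance = 1e-10)
  expect_equal(sol3$escape_probability, (1 / 3)^3, tolerance = 1e-10)
  expect_true(sol3$outbreak)
  expect_equal(solve_percolation(ens_regular3(T = 0.4))$q, 1,
               tolerance = 1e-8)
  # q_i >= 1 - T_i and the all-ones point is always a residual-0 fixed point
  expect_gte(sol3$q, 1 - 0.75)
  Fq1 <- 1 - 0.75 + 0.75 * gf_excess_layer(e3, 1, 1)
  expect_identical(Fq1, 1)
})

test_that("two-layer Poisson fixed points match the worked example", {
  e6 <- ens_two_poisson(50, 2, 0.1, 0.6)
  sol <- solve_percolation(e6)
  expect_equal(sol$q, c(0.9002, 0.4012), tolerance = 5e-4)
  # against the independent damped iteration oracle
  expect_equal(sol$q, oracle_fixed_point(e6, n_iter = 2000), tolerance = 1e-10)
  expect_equal(sol$escape_probability, gf_joint(e6, sol$q), tolerance = 1e-12)

  e6b <- ens_two_poisson(5, 2, 0.2, 0.6)
  solb <- solve_percolation(e6b)
  expect_equal(round(solb$q, 2), c(0.83, 0.49))
  expect_equal(solb$escape_probability, 0.156, tolerance = 1e-2)
})

test_that("iterates from zero are monotone and the map stays in the box", {
  e <- ens_two_poisson(5, 2, 0.2, 0.6)
  q <- rep(0, 2)
  prev <- q
  for (it in 1:200) {
    q <- vapply(1:2, function(i) {
      1 - e$T[i] + e$T[i] * gf_excess_layer(e, i, q)
    }, numeric(1))
    expect_true(all(q >= prev - 1e-14))
    expect_true(all(q >= 0 & q <= 1))
    prev <- q
  }
})

test_that("per-degree escape probabilities average to G(q)", {
  e <- ens_two_poisson(3, 2, 0.3, 0.6)
  sol <- solve_percolation(e)
  expect_equal(escape_probability(e, rep(1, 2)), 1)
  jp <- joint_pmf(e)
  per_deg <- vapply(seq_along(jp$prob), function(r) {
    escape_probability(e, sol$q, degree = jp$support[r, ])
  }, numeric(1))
  expect_equal(sum(jp$prob * per_deg), escape_probability(e, sol$q),
               tolerance = 1e-9)
})

test_that("outbreak condition tracks the per-layer reproduction numbers", {
  oc_hot <- outbreak_condition(ens_regular3(T = 0.75))
  expect_true(oc_hot$sufficient)
  expect_equal(oc_hot$r0_layers, 1.5)
  oc_cold <- outbreak_condition(ens_regular3(T = 0.4))
  expect_false(oc_cold$sufficient)
  # when sufficient, the solved fixed point is interior
  e <- ens_two_poisson(5, 2, 0.5, 0.7)
  oc <- outbreak_condition(e)
  expect_true(oc$sufficient)
  expect_true(all(solve_percolation(e)$q < 1))
})

test_that("transition scan locates unit-eigenvalue crossings", {
  path3 <- function(t) network_ensemble(
    degree_distribution("regular", k = 3), transmissibility = t)
  sc <- scan_transition(path3, seq(0.05, 0.95, by = 0.05),
                        bracket_tol = 1e-7, cross_check = TRUE)
  expect_equal(sc$t_star, 0.5, tolerance = 1e-6)
  expect_lt(sc$bracket_width, 1e-6)
  expect_true(sc$cross_check$ok)

  # crossing where T * Gtilde'(1) = 1 for a Poisson layer (Tc = 1/N)
  pathN <- function(t) network_ensemble(
    degree_distribution("poisson", mean = 4), transmissibility = t)
  scN <- scan_transition(pathN, seq(0.05, 0.95, by = 0.05))
  expect_lt(abs(scN$t_star - 0.25), 1e-6)

  # symmetric two-layer path T1 = T2 = t: lambda_+ = 3t, so t* = 1/3
  path5 <- function(t) ens_two_regular2(t, t)
  sc5 <- scan_transition(path5, seq(0.05, 0.95, by = 0.05))
  expect_lt(abs(sc5$t_star - 1 / 3), 1e-6)

  # no crossing on the grid: reported as absent, not an error
  flat <- scan_transition(path3, seq(0.05, 0.3, by = 0.05))
  expect_true(is.na(flat$t_star))
})

test_that("near-critical slope matches the closed form and finite differences", {
  e3 <- ens_regular3()
  ncs <- near_critical_slope(e3)
  expect_equal(ncs$coefficient, 12, tolerance = 1e-10)
  expect_equal(ncs$Tc, 0.5)

  # finite-difference slope of the solved P(T) just above threshold
  dT <- 1e-3
  eT <- ens_regular3(T = 0.5 + dT)
  P <- solve_percolation(eT)$escape_probability
  expect_equal((1 - P) / dT, 12, tolerance = 0.02)

  # Poisson layer: Tc = 1/N and coefficient 2N
  eN <- network_ensemble(degree_distribution("poisson", mean = 6),
                         transmissibility = 0.5)
  ncsN <- near_critical_slope(eN)
  expect_equal(ncsN$Tc, 1 / 6, tolerance = 1e-8)
  expect_equal(ncsN$coefficient, 12, tolerance = 1e-6)

  # degenerate: 2-regular has a linear excess pgf
  expect_error(near_critical_slope(
    network_ensemble(degree_distribution("regular", k = 2),
                     transmissibility = 0.5)), "degenerate")
  expect_error(near_critical_slope(ens_two_regular2()), "single-layer")
})

test_that("the printed quartic is satisfied by the nontrivial fixed point", {
  T1 <- 0.9; T2 <- 0.9
  sol <- solve_percolation(ens_two_regular2(T1, T2))
  expect_true(sol$outbreak)
  expect_lt(abs(example5_quartic(sol$q[2], T1, T2)), 1e-6)
  # and at an asymmetric supercritical point
  T1 <- 0.5; T2 <- 0.8
  sol2 <- solve_percolation(ens_two_regular2(T1, T2))
  expect_lt(abs(example5_quartic(sol2$q[2], T1, T2)), 1e-6)
})
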