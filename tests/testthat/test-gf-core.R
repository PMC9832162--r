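test_that("excess degree pmfs match their closed forms", {
  # single 3-regular layer: excess degree is the point mass at 2
  e3 <- ens_regular3()
  ep <- excess_joint_pmf(e3)
  expect_equal(unname(ep$support[, 1]), 2)
  expect_equal(ep$prob, 1)

  # single 2-regular layer: point mass at 1
  e2 <- network_ensemble(degree_distribution("regular", k = 2),
                         transmissibility = 0.7)
  ep2 <- excess_joint_pmf(e2)
  expect_equal(unname(ep2$support[, 1]), 1)

  # Poisson excess distribution is Poisson again:
  # oracle = direct evaluation of (k+1) P(k+1) / E(k)
  d <- degree_distribution("poisson", mean = 2)
  ep_d <- excess_joint_pmf(network_ensemble(d, transmissibility = 0.5))
  oracle <- (ep_d$support[, 1] + 1) * dpois(ep_d$support[, 1] + 1, 2) / 2
  expect_equal(ep_d$prob, oracle, tolerance = 1e-12)
  expect_equal(ep_d$prob, dpois(ep_d$support[, 1], 2), tolerance = 1e-12)

  # two 2-regular layers: following a layer-1 edge gives ramification (1, 2)
  e5 <- ens_two_regular2()
  lp <- layer_excess_pmf(e5, 1)
  expect_equal(unname(lp$support[1, ]), c(1, 2))
  expect_equal(lp$prob, 1)

  # mixture identity: Ptilde = sum_i E(k_i)/E(k) Ptilde_i
  e6 <- ens_two_poisson(3, 2, 0.2, 0.6)
  full <- excess_joint_pmf(e6)
  mk <- c(3, 2)
  mix_p <- rep(0, length(full$prob))
  key <- apply(full$support, 1, paste, collapse = ",")
  for (i in 1:2) {
    li <- layer_excess_pmf(e6, i)
    idx <- match(apply(li$support, 1, paste, collapse = ","), key)
    mix_p[idx[!is.na(idx)]] <- mix_p[idx[!is.na(idx)]] +
      mk[i] / sum(mk) * li$prob[!is.na(idx)]
  }
  expect_equal(full$prob, mix_p, tolerance = 1e-12)
  expect_equal(sum(full$prob), 1, tolerance = 1e-9)
})

test_that("multivariate generating functions evaluate correctly", {
  e3 <- ens_regular3()
  expect_equal(gf_excess(e3, 0.5), 0.25)          # Gtilde(x) = x^2
  expect_equal(gf_joint(e3, 0.5), 0.125)          # G(x) = x^3
  expect_equal(gf_excess(e3, 1), 1)

  # two Poisson layers: Gtilde_i(x) = exp(-N1(1-x1) - N2(1-x2))
  e6 <- ens_two_poisson(50, 2, 0.1, 0.6)
  expect_equal(gf_excess(e6, c(0.9, 0.4)), exp(-50 * 0.1 - 2 * 0.6),
               tolerance = 1e-10)
  expect_equal(gf_excess_layer(e6, 1, c(1, 0)), exp(-2), tolerance = 1e-10)
  expect_equal(gf_excess(e6, c(1, 1)), 1, tolerance = 1e-10)

  # two 2-regular layers: Gtilde_1 = x1 x2^2
  e5 <- ens_two_regular2()
  expect_equal(gf_excess_layer(e5, 1, c(0.5, 0.5)), 0.125)
  expect_equal(gf_excess_layer(e5, 1, c(1, 1)), 1)

  # generating functions agree with the pmf-weighted power sums
  jp <- excess_joint_pmf(e6)
  x <- c(0.8, 0.6)
  direct <- sum(jp$prob * x[1]^jp$support[, 1] * x[2]^jp$support[, 2])
  expect_equal(gf_excess(e6, x), direct, tolerance = 1e-10)
})

test_that("mixture identity for Gtilde holds on a grid", {
  e <- network_ensemble(degree_distribution("poisson", mean = 3),
                        degree_distribution("regular", k = 2),
                        transmissibility = c(0.3, 0.7))
  mk <- c(3, 2)
  for (x1 in c(0.1, 0.5, 0.9)) {
    for (x2 in c(0.2, 0.8, 1)) {
      x <- c(x1, x2)
      mix <- (mk[1] * gf_excess_layer(e, 1, x) +
                mk[2] * gf_excess_layer(e, 2, x)) / sum(mk)
      expect_equal(gf_excess(e, x), mix, tolerance = 1e-10)
    }
  }
})

test_that("closed-form gradients agree with central finite differences", {
  e <- network_ensemble(degree_distribution("poisson", mean = 3),
                        degree_distribution("geometric", mean = 2),
                        transmissibility = c(0.3, 0.7))
  x <- c(0.6, 0.7)
  expect_equal(gf_excess(e, x, grad = TRUE),
               fd_gradient(function(z) gf_excess(e, z), x),
               tolerance = 1e-6)
  expect_equal(gf_excess_layer(e, 1, x, grad = TRUE),
               fd_gradient(function(z) gf_excess_layer(e, 1, z), x),
               tolerance = 1e-6)
  expect_equal(gf_joint(e, x, grad = TRUE),
               fd_gradient(function(z) gf_joint(e, z), x),
               tolerance = 1e-6)
  expect_equal(gf_H_layer(e, 2, x, s0 = 0.9, grad = TRUE),
               fd_gradient(function(z) gf_H_layer(e, 2, z, s0 = 0.9), x),
               tolerance = 1e-6)
})

test_that("susceptibility-weighted pgf Htilde has the stated properties", {
  e5 <- ens_two_regular2()
  # s0 = 1: Htilde_1 = x1 * Gtilde_1 on a grid
  for (x1 in c(0.2, 0.5, 1)) {
    for (x2 in c(0.4, 0.5, 1)) {
      x <- c(x1, x2)
      expect_equal(gf_H_layer(e5, 1, x, s0 = 1), x[1] * gf_excess_layer(e5, 1, x),
                   tolerance = 1e-12)
    }
  }
  expect_equal(gf_H_layer(e5, 1, c(0.5, 0.5), s0 = 1), 0.0625)
  # Htilde_i(1) = E[s(0) | layer i]
  expect_equal(gf_H_layer(e5, 1, c(1, 1), s0 = 0.9), 0.9)

  # per-degree table agrees with the constant closed form
  jp <- layer_excess_pmf(e5, 1)
  kfull <- jp$support; kfull[, 1] <- kfull[, 1] + 1
  tab <- as.data.frame(rbind(kfull, as.matrix(joint_pmf(e5)$support)))
  tab <- unique(tab)
  tab$s <- 0.8
  s0_tab <- initial_susceptibility(table = tab)
  expect_equal(gf_H_layer(e5, 1, c(0.5, 0.7), s0 = s0_tab),
               gf_H_layer(e5, 1, c(0.5, 0.7), s0 = 0.8), tolerance = 1e-12)
  # missing joint degrees are reported
  s0_bad <- initial_susceptibility(table = data.frame(k1 = 0, k2 = 0, s = 1))
  expect_error(gf_H_layer(e5, 2, c(0.5, 0.7), s0 = s0_bad), "missing")
})

test_that("secondary-infection pgf and R0 follow the excess machinery", {
  e3 <- ens_regular3(T = 0.5)
  expect_equal(secondary_infection_pgf(e3, 1), 1)
  expect_equal(secondary_infection_pgf(e3, 0), 0.25)  # Gtilde(1 - T) = 0.5^2
  # oracle: binomial thinning of the excess degree (2 with prob 1)
  expect_equal(secondary_infection_pgf(e3, 0), dbinom(0, 2, 0.5))
  expect_equal(r0(e3), 1)                              # T * Gtilde'(1) = 0.5*2

  # Poisson: R0 = T * N
  eN <- network_ensemble(degree_distribution("poisson", mean = 7),
                         transmissibility = 0.3)
  expect_equal(r0(eN), 2.1, tolerance = 1e-9)

  e6 <- ens_two_poisson(50, 2, 0.1, 0.6)
  expect_equal(r0(e6), 6.2, tolerance = 1e-9)

  # derivative of the secondary pgf at 1 equals R0 (finite differences)
  h <- 1e-6
  fd <- (secondary_infection_pgf(e6, 1) -
           secondary_infection_pgf(e6, 1 - h)) / h
  expect_equal(fd, r0(e6), tolerance = 1e-4)
})

test_that("per-layer reproduction numbers and the weighting identity hold", {
  e5 <- ens_two_regular2(0.25, 0.5)
  expect_equal(r0_layer(e5, 1), 0.25 + 2 * 0.5)   # Gtilde_1 = x1 x2^2
  # single layer: r0_layer == r0
  e3 <- ens_regular3(0.6)
  expect_equal(r0_layer(e3, 1), r0(e3))
  # R0 = sum_i E(k_i)/E(k) R0(i) for a heterogeneous ensemble
  e <- network_ensemble(degree_distribution("poisson", mean = 3),
                        degree_distribution("geometric", mean = 2),
                        transmissibility = c(0.3, 0.7))
  mk <- vapply(e$layers, mean_degree, numeric(1))
  mix <- sum(mk / sum(mk) *
               vapply(1:2, function(i) r0_layer(e, i), numeric(1)))
  expect_equal(r0(e), mix, tolerance = 1e-10)
})

test_that("reproduction matrices match worked examples and identities", {
  # two 2-regular layers with T = (0.25, 0.5): entries from Gtilde_i = x_i x_j^2
  e5 <- ens_two_regular2(0.25, 0.5)
  R <- r_matrix(e5, "Gtilde")
  expect_equal(R$entries, matrix(c(0.25, 0.5, 1.0, 0.5), 2, 2),
               tolerance = 1e-12)
  # row sums are the per-layer reproduction numbers
  expect_equal(rowSums(R$entries),
               vapply(1:2, function(i) r0_layer(e5, i), numeric(1)),
               tolerance = 1e-12)
  # closed-form eigenvalue: (T1+T2)/2 + sqrt(T1^2+T2^2+14 T1 T2)/2
  lam_closed <- (0.25 + 0.5) / 2 + sqrt(0.25^2 + 0.5^2 + 14 * 0.25 * 0.5) / 2
  expect_equal(R$leading_eigenvalue, lam_closed, tolerance = 1e-10)
  expect_equal(R$leading_eigenvalue, leading_eigen(t(R$entries))$value,
               tolerance = 1e-12)   # transposition-invariant

  # two Poisson layers: rank-1 matrix with rows (T1 N1, T2 N2)
  e6 <- ens_two_poisson(50, 2, 0.1, 0.6)
  R6 <- r_matrix(e6, "Gtilde")
  expect_equal(R6$entries, matrix(c(5, 5, 1.2, 1.2), 2, 2),
               tolerance = 1e-8)
  expect_equal(sort(Re(R6$eigenvalues)), c(0, 6.2), tolerance = 1e-8)
  expect_equal(R6$leading_eigenvalue, 0.1 * 50 + 0.6 * 2, tolerance = 1e-8)

  # general 2-layer moment formula (diagonal T_i G''_i(1)/G'_i(1),
  # off-diagonal T_j G'_j(1)), checked against finite differences
  e <- network_ensemble(degree_distribution("poisson", mean = 3),
                        degree_distribution("geometric", mean = 2),
                        transmissibility = c(0.3, 0.7))
  Rg <- r_matrix(e, "Gtilde")$entries
  for (i in 1:2) {
    fd <- fd_gradient(function(z) gf_excess_layer(e, i, z), c(1, 1), h = 1e-7)
    expect_equal(Rg[i, ], e$T * fd, tolerance = 1e-5)
  }

  # Remark-7 identity: R^Htilde (s0 = 1) = diag(T) + R^Gtilde
  Rh <- r_matrix(e, "Htilde", s0 = 1)
  expect_equal(Rh$entries, diag(e$T) + Rg, tolerance = 1e-12)
  # constant s0 scales the Htilde matrix
  Rh9 <- r_matrix(e, "Htilde", s0 = 0.9)
  expect_equal(Rh9$entries, 0.9 * (diag(e$T) + Rg), tolerance = 1e-12)
  expect_error(r_matrix(e, "Htilde"), "s0")

  # identity-scaled matrix: leading eigenvalue c
  expect_equal(leading_eigen(diag(c(0.4, 0.4)))$value, 0.4)
})
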