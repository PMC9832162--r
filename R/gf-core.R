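#' Joint degree pmf of an ensemble
#'
#' The joint probability that a random vertex has degrees `(k_1, ..., k_n)`
#' across the layers. Layers are independent, so the joint pmf is the product
#' of the per-layer (truncated) pmfs.
#'
#' @param e A [network_ensemble()].
#' @return An object of class `joint_pmf`: a list with `support` (integer
#'   matrix, one joint degree per row), `prob` and `n`.
#' @export
joint_pmf <- function(e) {
  stopifnot(inherits(e, "network_ensemble"))
  grids <- lapply(e$layers, function(d) d$degrees)
  support <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(support) <- paste0("k", seq_len(e$n))
  prob <- rep(1, nrow(support))
  for (i in seq_len(e$n)) {
    prob <- prob * e$layers[[i]]$pmf[support[, i] + 1L]
  }
  new_joint_pmf(support, prob, e$n)
}

new_joint_pmf <- function(support, prob, n) {
  keep <- prob > 0
  structure(list(support = support[keep, , drop = FALSE], prob = prob[keep],
                 n = n),
            class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("<joint_pmf: %d layers, %d support points, total mass %.12g>\n",
              x$n, length(x$prob), sum(x$prob)))
  invisible(x)
}

#' Joint excess-degree (ramification) pmf
#'
#' Distribution of the number of onward edges, by layer, of a vertex reached
#' by following a uniformly random edge of the whole network:
#' `Ptilde(k) = sum_l (k_l + 1) P_l(k_l + 1) prod_{i != l} P_i(k_i) / E(k)`.
#' Equals the mean-degree-weighted mixture of the per-layer excess pmfs of
#' [layer_excess_pmf()].
#'
#' @param e A [network_ensemble()].
#' @return A `joint_pmf` over excess degrees.
#' @export
excess_joint_pmf <- function(e) {
  stopifnot(inherits(e, "network_ensemble"))
  mk <- layer_means(e)
  if (sum(mk) <= 0) {
    stop("degenerate ensemble: total mean degree is zero", call. = FALSE)
  }
  acc <- NULL
  for (l in seq_len(e$n)) {
    if (mk[l] == 0) next
    part <- layer_excess_pmf(e, l)
    w <- mk[l] / sum(mk)
    if (is.null(acc)) {
      acc <- list(support = part$support, prob = w * part$prob)
    } else {
      # supports share the same expand.grid layout only if truncations match;
      # merge by key to stay safe
      acc <- merge_joint(acc, part, w)
    }
  }
  new_joint_pmf(acc$support, acc$prob, e$n)
}

merge_joint <- function(acc, part, w) {
  key_a <- apply(acc$support, 1, paste, collapse = ",")
  key_p <- apply(part$support, 1, paste, collapse = ",")
  idx <- match(key_p, key_a)
  new <- is.na(idx)
  prob <- acc$prob
  prob[idx[!new]] <- prob[idx[!new]] + w * part$prob[!new]
  list(support = rbind(acc$support, part$support[new, , drop = FALSE]),
       prob = c(prob, w * part$prob[new]))
}

#' Excess-degree pmf after following a layer-i edge
#'
#' Distribution of the onward degrees of a vertex reached along a random edge
#' of layer `i`:
#' `Ptilde_i(k) = (k_i + 1) P_i(k_i + 1) prod_{j != i} P_j(k_j) / E(k_i)`.
#'
#' @param e A [network_ensemble()].
#' @param i Layer index.
#' @return A `joint_pmf` over excess degrees.
#' @export
layer_excess_pmf <- function(e, i) {
  stopifnot(inherits(e, "network_ensemble"))
  mki <- mean_degree(e$layers[[i]])
  if (mki <= 0) {
    stop(sprintf("degenerate layer %d: mean degree is zero", i),
         call. = FALSE)
  }
  grids <- lapply(seq_len(e$n), function(j) {
    d <- e$layers[[j]]
    if (j == i) 0:max(d$truncation_K - 1L, 0L) else d$degrees
  })
  support <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(support) <- paste0("k", seq_len(e$n))
  prob <- rep(1, nrow(support))
  for (j in seq_len(e$n)) {
    d <- e$layers[[j]]
    if (j == i) {
      prob <- prob * (support[, j] + 1) * d$pmf[support[, j] + 2L] / mki
    } else {
      prob <- prob * d$pmf[support[, j] + 1L]
    }
  }
  new_joint_pmf(support, prob, e$n)
}

#' Multivariate generating functions of an ensemble
#'
#' `gf_joint` evaluates the joint degree pgf
#' `G(x) = prod_i G_i(x_i)`; `gf_excess` evaluates the whole-network excess
#' pgf `Gtilde(x) = sum_l G_l'(x_l) prod_{i != l} G_i(x_i) / E(k)`; and
#' `gf_excess_layer` evaluates the layer-`i` excess pgf
#' `Gtilde_i(x) = G_i'(x_i) / G_i'(1) * prod_{j != i} G_j(x_j)`.
#' With `grad = TRUE` the gradient vector is returned instead of the value.
#'
#' @param e A [network_ensemble()].
#' @param x Numeric vector of length `n` in `[0, 1]^n`.
#' @param grad If `TRUE`, return the gradient with respect to `x`.
#' @return A single number, or an `n`-vector when `grad = TRUE`.
#' @export
gf_joint <- function(e, x, grad = FALSE) {
  check_point(e, x)
  g  <- vapply(seq_len(e$n), function(i) pgf(e$layers[[i]], x[i]), numeric(1))
  if (!grad) return(prod(g))
  g1 <- vapply(seq_len(e$n), function(i) pgf(e$layers[[i]], x[i], 1),
               numeric(1))
  vapply(seq_len(e$n), function(j) g1[j] * prod(g[-j]), numeric(1))
}

#' @rdname gf_joint
#' @export
gf_excess <- function(e, x, grad = FALSE) {
  check_point(e, x)
  mk <- layer_means(e)
  if (sum(mk) <= 0) {
    stop("degenerate ensemble: total mean degree is zero", call. = FALSE)
  }
  w <- mk / sum(mk)
  parts <- lapply(which(mk > 0), function(l) gf_excess_layer(e, l, x, grad))
  out <- 0
  for (idx in seq_along(parts)) {
    out <- out + w[which(mk > 0)][idx] * parts[[idx]]
  }
  out
}

#' @rdname gf_joint
#' @param i Layer index (for `gf_excess_layer`).
#' @export
gf_excess_layer <- function(e, i, x, grad = FALSE) {
  check_point(e, x)
  di <- e$layers[[i]]
  mki <- mean_degree(di)
  if (mki <= 0) {
    stop(sprintf("degenerate layer %d: mean degree is zero", i),
         call. = FALSE)
  }
  g  <- vapply(seq_len(e$n), function(j) pgf(e$layers[[j]], x[j]), numeric(1))
  gi1 <- pgf(di, x[i], 1)
  if (!grad) {
    return(gi1 / mki * prod(g[-i]))
  }
  g1 <- vapply(seq_len(e$n), function(j) pgf(e$layers[[j]], x[j], 1),
               numeric(1))
  gi2 <- pgf(di, x[i], 2)
  vapply(seq_len(e$n), function(j) {
    if (j == i) {
      gi2 / mki * prod(g[-i])
    } else {
      gi1 / mki * g1[j] * prod(g[-c(i, j)])
    }
  }, numeric(1))
}

check_point <- function(e, x) {
  stopifnot(inherits(e, "network_ensemble"))
  if (!is.numeric(x) || length(x) != e$n) {
    stop(sprintf("`x` must be a numeric vector of length %d", e$n),
         call. = FALSE)
  }
  if (any(x < -1e-12 | x > 1 + 1e-12)) {
    stop("`x` must lie in [0, 1]^n", call. = FALSE)
  }
  invisible(TRUE)
}

#' Susceptibility-weighted excess generating function
#'
#' Evaluates `Htilde_i(x) = sum_k Ptilde_i(k) s_{(k + e_i)} x^(k + e_i)`,
#' the layer-`i` excess pgf reweighted by the initial susceptibility of the
#' reached vertex (whose full degree is its excess degree plus the arrival
#' edge). For a constant susceptibility `c` this reduces to
#' `c * x_i * Gtilde_i(x)`; in particular `Htilde_i == x_i * Gtilde_i` when
#' everyone starts susceptible. `Htilde_i(1, ..., 1)` equals the mean initial
#' susceptibility of vertices reached along layer-`i` edges.
#'
#' @param e A [network_ensemble()].
#' @param i Layer index.
#' @param x Numeric vector of length `n` in `[0, 1]^n`.
#' @param s0 Initial susceptibility: a constant in `[0, 1]` or an
#'   [initial_susceptibility()] object.
#' @param grad If `TRUE`, return the gradient with respect to `x`.
#' @return A single number, or an `n`-vector when `grad = TRUE`.
#' @export
gf_H_layer <- function(e, i, x, s0 = 1, grad = FALSE) {
  check_point(e, x)
  s0 <- as_s0(s0)
  if (s0$mode == "constant") {
    if (!grad) return(s0$s0 * x[i] * gf_excess_layer(e, i, x))
    gval <- gf_excess_layer(e, i, x)
    ggrad <- gf_excess_layer(e, i, x, grad = TRUE)
    out <- s0$s0 * x[i] * ggrad
    out[i] <- out[i] + s0$s0 * gval
    return(out)
  }
  # per-degree table: finite sum over the excess support
  jp <- layer_excess_pmf(e, i)
  kfull <- jp$support
  kfull[, i] <- kfull[, i] + 1L   # reached vertex's full degree
  s <- s0_lookup(s0, kfull)
  if (!grad) {
    terms <- jp$prob * s
    for (j in seq_len(e$n)) terms <- terms * x[j]^kfull[, j]
    return(sum(terms))
  }
  vapply(seq_len(e$n), function(j) {
    terms <- jp$prob * s * kfull[, j] * safe_pow(x[j], kfull[, j] - 1)
    for (l in seq_len(e$n)) {
      if (l != j) terms <- terms * x[l]^kfull[, l]
    }
    sum(terms)
  }, numeric(1))
}

# x^p with the convention 0 * x^(-1) -> 0 handled by the caller's k factor
safe_pow <- function(x, p) {
  out <- numeric(length(p))
  pos <- p >= 0
  out[pos] <- x^p[pos]
  out
}

#' Generating function of the secondary-infection count
#'
#' Pgf of the number `M` of onward infections caused by a randomly infected
#' individual in an otherwise susceptible population:
#' `G_M(x) = Gtilde(1 + T_1 (x - 1), ..., 1 + T_n (x - 1))`. Its derivative
#' at 1 is the basic reproduction number [r0()]; its power-series coefficients
#' are the offspring distribution (binomial thinning of the excess degrees by
#' the layer transmissibilities).
#'
#' @param e A [network_ensemble()].
#' @param x Evaluation points in `[0, 1]` (vectorised).
#' @return Numeric vector of `G_M(x)` values.
#' @export
secondary_infection_pgf <- function(e, x) {
  stopifnot(inherits(e, "network_ensemble"))
  if (any(x < -1e-12 | x > 1 + 1e-12)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  vapply(x, function(xx) gf_excess(e, 1 + e$T * (xx - 1)), numeric(1))
}

#' Basic reproduction number and per-layer variants
#'
#' `r0` computes `R0 = sum_j T_j dGtilde/dx_j` at the all-ones point, the mean
#' number of secondary infections caused by a typical newly infected vertex.
#' `r0_layer` computes `R0(i) = sum_j T_j dGtilde_i/dx_j` at all-ones: the
#' mean number of onward infections caused by individuals who were themselves
#' infected along a layer-`i` edge. The identity
#' `R0 = sum_i E(k_i)/E(k) * R0(i)` holds.
#'
#' @param e A [network_ensemble()].
#' @param i Layer index (for `r0_layer`).
#' @return A single number.
#' @export
r0 <- function(e) {
  stopifnot(inherits(e, "network_ensemble"))
  sum(e$T * gf_excess(e, rep(1, e$n), grad = TRUE))
}

#' @rdname r0
#' @export
r0_layer <- function(e, i) {
  stopifnot(inherits(e, "network_ensemble"))
  sum(e$T * gf_excess_layer(e, i, rep(1, e$n), grad = TRUE))
}

#' Reproduction matrices
#'
#' Builds the `n x n` reproduction matrix whose entry `(i, j)` is
#' `T_j * dGtilde_i/dx_j` at the all-ones point (`kernel = "Gtilde"`), or
#' `T_j * dHtilde_i/dx_j` (`kernel = "Htilde"`, which requires an initial
#' susceptibility). Entry `(i, j)` is the expected number of layer-`j`
#' transmissions caused by a vertex that was itself reached along a layer-`i`
#' edge; note that several published examples print the transpose of this
#' orientation. All spectral quantities are orientation-invariant. Row sums of
#' the `Gtilde` matrix are the per-layer reproduction numbers [r0_layer()],
#' and with everyone initially susceptible the `Htilde` matrix equals
#' `diag(T) + ` the `Gtilde` matrix.
#'
#' @param e A [network_ensemble()].
#' @param kernel `"Gtilde"` or `"Htilde"`.
#' @param s0 Initial susceptibility (required for `kernel = "Htilde"`).
#' @return An object of class `rmatrix`: list with `kernel`, `entries`,
#'   `leading_eigenvalue`, `leading_eigenvector`, `eigenvalues`.
#' @export
r_matrix <- function(e, kernel = c("Gtilde", "Htilde"), s0 = NULL) {
  stopifnot(inherits(e, "network_ensemble"))
  kernel <- match.arg(kernel)
  n <- e$n
  ones <- rep(1, n)
  entries <- matrix(0, n, n)
  for (i in seq_len(n)) {
    gr <- if (kernel == "Gtilde") {
      gf_excess_layer(e, i, ones, grad = TRUE)
    } else {
      if (is.null(s0)) {
        stop("kernel = \"Htilde\" requires `s0`", call. = FALSE)
      }
      gf_H_layer(e, i, ones, s0 = s0, grad = TRUE)
    }
    entries[i, ] <- e$T * gr
  }
  le <- perron_eigen(entries)
  structure(
    list(kernel = kernel, entries = entries,
         leading_eigenvalue = le$value, leading_eigenvector = le$vector,
         eigenvalues = le$all),
    class = "rmatrix"
  )
}

#' @export
print.rmatrix <- function(x, ...) {
  cat(sprintf("<rmatrix: %s kernel, %d x %d>\n", x$kernel,
              nrow(x$entries), ncol(x$entries)))
  print(x$entries)
  cat(sprintf("  spectral radius %.8g\n", x$leading_eigenvalue))
  invisible(x)
}

#' Spectral radius and Perron vector of a reproduction matrix
#'
#' Returns the leading (Perron) eigenvalue -- the spectral radius -- and an
#' associated nonnegative eigenvector. Invariant under transposition of the
#' matrix, so unaffected by the orientation convention of [r_matrix()].
#'
#' @param R An `rmatrix` or a plain nonnegative square matrix.
#' @return List with `value` (spectral radius) and `vector` (nonnegative
#'   eigenvector, unit 1-norm).
#' @export
leading_eigen <- function(R) {
  m <- if (inherits(R, "rmatrix")) R$entries else as.matrix(R)
  le <- perron_eigen(m)
  list(value = le$value, vector = le$vector)
}

perron_eigen <- function(m) {
  ev <- eigen(m)
  mod <- Mod(ev$values)
  lead <- which.max(mod)
  vec <- ev$vectors[, lead]
  if (max(abs(Im(vec))) < 1e-9) {
    vec <- Re(vec)
    if (sum(vec) < 0) vec <- -vec
    vec <- pmax(vec, 0)
    if (sum(vec) > 0) vec <- vec / sum(vec)
  } else {
    vec <- abs(vec) / sum(abs(vec))
  }
  list(value = mod[lead], vector = vec, all = ev$values)
}
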