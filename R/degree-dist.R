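#' Degree distributions for network layers
#'
#' Construct the degree distribution of one contact layer. The distribution is
#' stored as a finite probability mass function over degrees `0..K`, truncated
#' at the smallest `K` whose tail mass is below `tail_tol`. Closed-form
#' probability generating functions (pgfs) are used for the `regular`,
#' `poisson` and `geometric` families; `powerlaw` and `empirical` pmfs are
#' handled as truncated polynomials.
#'
#' Families and their parameters:
#' \describe{
#'   \item{regular}{`k`: every vertex has exactly `k` contacts in the layer.}
#'   \item{poisson}{`mean`: Poisson-distributed degrees with the given mean.}
#'   \item{geometric}{`mean`: geometric degrees on `0, 1, 2, ...` with the
#'     given mean, i.e. `P(k) = (1 - p) p^k` with `p = mean / (1 + mean)`.}
#'   \item{powerlaw}{`exponent` (> 1), optional `kmin` (default 1) and `kmax`
#'     (default 10000): `P(k)` proportional to `k^-exponent` on
#'     `kmin..kmax`, normalised over that finite support.}
#'   \item{empirical}{`pmf`: numeric vector of probabilities over degrees
#'     `0..(length(pmf) - 1)`; must sum to 1 within `tail_tol` and is
#'     renormalised.}
#' }
#'
#' @param family One of `"regular"`, `"poisson"`, `"geometric"`,
#'   `"powerlaw"`, `"empirical"`.
#' @param ... Family-specific parameters, see Details.
#' @param tail_tol Truncation tolerance in `(0, 1e-4]`: the pmf is cut at the
#'   smallest degree `K` such that `P(degree > K) < tail_tol`.
#' @return An object of class `degree_distribution` with elements `family`,
#'   `params`, `degrees`, `pmf`, `truncation_K`, `tail_mass`, `tail_tol`.
#' @examples
#' d <- degree_distribution("poisson", mean = 2)
#' mean_degree(d)
#' pgf(d, 0.5)            # exp(-2 * 0.5)
#' @export
degree_distribution <- function(family = c("regular", "poisson", "geometric",
                                           "powerlaw", "empirical"),
                                ..., tail_tol = 1e-10) {
  family <- match.arg(family)
  if (!is.numeric(tail_tol) || length(tail_tol) != 1 ||
      tail_tol <= 0 || tail_tol > 1e-4) {
    stop("`tail_tol` must be a single number in (0, 1e-4]", call. = FALSE)
  }
  params <- list(...)

  out <- switch(family,
    regular = {
      k <- params$k
      if (is.null(k) || !is.numeric(k) || length(k) != 1 || k < 0 ||
          k != round(k)) {
        stop("regular family requires a single nonnegative integer `k`",
             call. = FALSE)
      }
      pmf <- c(rep(0, k), 1)
      list(params = list(k = k), pmf = pmf, K = k, tail_mass = 0)
    },
    poisson = {
      m <- params$mean
      if (is.null(m) || !is.numeric(m) || length(m) != 1 || m <= 0) {
        stop("poisson family requires a single positive `mean`", call. = FALSE)
      }
      K <- stats::qpois(1 - tail_tol, m)
      # qpois guarantees P(X <= K) >= 1 - tail_tol; nudge up if rounding bites
      while (stats::ppois(K, m) < 1 - tail_tol) K <- K + 1
      pmf <- stats::dpois(0:K, m)
      list(params = list(mean = m), pmf = pmf, K = K,
           tail_mass = 1 - sum(pmf))
    },
    geometric = {
      m <- params$mean
      if (is.null(m) || !is.numeric(m) || length(m) != 1 || m <= 0) {
        stop("geometric family requires a single positive `mean`",
             call. = FALSE)
      }
      p <- m / (1 + m)   # P(k) = (1 - p) p^k, mean p/(1-p) = m
      K <- stats::qgeom(1 - tail_tol, prob = 1 - p)
      while (stats::pgeom(K, prob = 1 - p) < 1 - tail_tol) K <- K + 1
      pmf <- stats::dgeom(0:K, prob = 1 - p)
      list(params = list(mean = m, p = p), pmf = pmf, K = K,
           tail_mass = 1 - sum(pmf))
    },
    powerlaw = {
      a <- params$exponent
      kmin <- if (is.null(params$kmin)) 1L else as.integer(params$kmin)
      kmax <- if (is.null(params$kmax)) 10000L else as.integer(params$kmax)
      if (is.null(a) || !is.numeric(a) || length(a) != 1 || a <= 1) {
        stop("powerlaw family requires a single `exponent` > 1", call. = FALSE)
      }
      if (kmin < 1 || kmax <= kmin) {
        stop("powerlaw requires 1 <= kmin < kmax", call. = FALSE)
      }
      w <- c(rep(0, kmin), (kmin:kmax)^(-a))
      pmf <- w / sum(w)
      list(params = list(exponent = a, kmin = kmin, kmax = kmax),
           pmf = pmf, K = kmax, tail_mass = 0)
    },
    empirical = {
      pmf <- params$pmf
      if (is.null(pmf) || !is.numeric(pmf) || any(pmf < 0)) {
        stop("empirical family requires a nonnegative numeric `pmf` vector",
             call. = FALSE)
      }
      s <- sum(pmf)
      if (abs(s - 1) > tail_tol) {
        stop(sprintf(
          "empirical pmf sums to %.12g, outside [1 - tail_tol, 1 + tail_tol]",
          s), call. = FALSE)
      }
      pmf <- pmf / s
      # trim trailing zero-probability degrees
      K <- max(which(pmf > 0)) - 1L
      pmf <- pmf[seq_len(K + 1)]
      list(params = list(), pmf = pmf, K = K, tail_mass = 0)
    }
  )

  structure(
    list(family = family, params = out$params, degrees = 0:out$K,
         pmf = out$pmf, truncation_K = out$K, tail_mass = out$tail_mass,
         tail_tol = tail_tol),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution: %s>\n", x$family))
  if (length(x$params)) {
    cat("  params:",
        paste(names(x$params), unlist(x$params), sep = " = ",
              collapse = ", "), "\n")
  }
  cat(sprintf("  support 0..%d, mean degree %.6g, tail mass %.3g\n",
              x$truncation_K, mean_degree(x), x$tail_mass))
  invisible(x)
}

#' Mean degree of a layer
#'
#' Returns the first pgf derivative at 1, i.e. the expected degree
#' `sum(k * P(k))`. Exact for the closed-form families.
#'
#' @param d A [degree_distribution()].
#' @return The mean degree, a single number.
#' @export
mean_degree <- function(d) {
  stopifnot(inherits(d, "degree_distribution"))
  switch(d$family,
    regular   = d$params$k,
    poisson   = d$params$mean,
    geometric = d$params$mean,
    sum(d$degrees * d$pmf)
  )
}

#' Evaluate a layer's probability generating function
#'
#' Computes `G(x) = sum_k P(k) x^k` or its first or second derivative at `x`.
#' Closed forms are used for the `regular`, `poisson` and `geometric`
#' families; the finite pmf sum otherwise. The two routes agree to truncation
#' accuracy and are cross-checked in the test suite.
#'
#' @param d A [degree_distribution()].
#' @param x Evaluation points in `[0, 1]` (vectorised).
#' @param order Derivative order, 0, 1 or 2.
#' @return Numeric vector of the same length as `x`.
#' @export
pgf <- function(d, x, order = 0) {
  stopifnot(inherits(d, "degree_distribution"))
  if (!order %in% 0:2) {
    stop("`order` must be 0, 1 or 2 (higher derivatives unsupported)",
         call. = FALSE)
  }
  if (any(x < -1e-12 | x > 1 + 1e-12)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  switch(d$family,
    regular = {
      k <- d$params$k
      switch(as.character(order),
        "0" = x^k,
        "1" = if (k >= 1) k * x^(k - 1) else 0 * x,
        "2" = if (k >= 2) k * (k - 1) * x^(k - 2) else 0 * x)
    },
    poisson = {
      m <- d$params$mean
      m^order * exp(-m * (1 - x))
    },
    geometric = {
      p <- d$params$p
      base <- (1 - p) / (1 - p * x)
      switch(as.character(order),
        "0" = base,
        "1" = p * (1 - p) / (1 - p * x)^2,
        "2" = 2 * p^2 * (1 - p) / (1 - p * x)^3)
    },
    pgf_sum(d$pmf, d$degrees, x, order)
  )
}

# truncated-polynomial pgf evaluation (used for empirical/powerlaw and as the
# independent cross-check of the closed forms)
pgf_sum <- function(pmf, degrees, x, order) {
  coef <- switch(as.character(order),
    "0" = pmf,
    "1" = degrees * pmf,
    "2" = degrees * (degrees - 1) * pmf)
  pow <- pmax(degrees - order, 0)
  keep <- coef != 0
  vapply(x, function(xx) sum(coef[keep] * xx^pow[keep]), numeric(1))
}
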