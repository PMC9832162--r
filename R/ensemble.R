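#' Multilayer network ensemble
#'
#' Bundles `n` contact layers, each described by a [degree_distribution()] and
#' a per-edge transmissibility `T_i` in `[0, 1]`. Layers are statistically
#' independent: the joint degree pmf is the product of the per-layer pmfs, and
#' the joint pgf factorises as `G(x_1, ..., x_n) = prod_i G_i(x_i)`. Layer
#' order is significant and preserved.
#'
#' @param ... One or more [degree_distribution()] objects (alternatively a
#'   single list of them).
#' @param transmissibility Numeric vector of per-layer transmissibilities in
#'   `[0, 1]`, one per layer.
#' @return An object of class `network_ensemble` with elements `layers`
#'   (list of degree distributions), `T` (transmissibilities) and `n`.
#' @examples
#' e <- network_ensemble(
#'   degree_distribution("poisson", mean = 50),
#'   degree_distribution("poisson", mean = 2),
#'   transmissibility = c(0.1, 0.6)
#' )
#' r0(e)   # 0.1 * 50 + 0.6 * 2 = 6.2
#' @export
network_ensemble <- function(..., transmissibility) {
  layers <- list(...)
  if (length(layers) == 1 && !inherits(layers[[1]], "degree_distribution") &&
      is.list(layers[[1]])) {
    layers <- layers[[1]]
  }
  if (length(layers) < 1) stop("at least one layer is required", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "degree_distribution")
  if (!all(ok)) {
    stop("all layers must be degree_distribution objects", call. = FALSE)
  }
  if (!is.numeric(transmissibility) ||
      length(transmissibility) != length(layers)) {
    stop("`transmissibility` must supply one value per layer", call. = FALSE)
  }
  if (any(transmissibility < 0 | transmissibility > 1)) {
    stop("all transmissibilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(layers = layers, T = as.numeric(transmissibility),
         n = length(layers)),
    class = "network_ensemble"
  )
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat(sprintf("<network_ensemble: %d layer%s>\n", x$n,
              if (x$n > 1) "s" else ""))
  for (i in seq_len(x$n)) {
    d <- x$layers[[i]]
    cat(sprintf("  [%d] %s (mean degree %.4g), T = %g\n",
                i, d$family, mean_degree(d), x$T[i]))
  }
  cat(sprintf("  R0 = %.6g\n", r0(x)))
  invisible(x)
}

# per-layer mean degrees E(k_i) and total E(k)
layer_means <- function(e) vapply(e$layers, mean_degree, numeric(1))

#' Initial susceptibility specification
#'
#' Describes the initial fraction of susceptibles entering the modified
#' generating functions `H_i` and the degree-based mean-field system. Either a
#' single constant (degree-independent) or a per-joint-degree table.
#'
#' @param value Constant initial susceptibility in `[0, 1]`
#'   (degree-independent mode).
#' @param table Data frame with one column `k1, ..., kn` per layer plus a
#'   column `s` of values in `[0, 1]` (per-degree mode). Joint degrees needed
#'   by an evaluation but missing from the table raise an error.
#' @return An object of class `initial_susceptibility`.
#' @export
initial_susceptibility <- function(value = NULL, table = NULL) {
  if (is.null(value) == is.null(table)) {
    stop("supply exactly one of `value` or `table`", call. = FALSE)
  }
  if (!is.null(value)) {
    if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1) {
      stop("constant initial susceptibility must be a single value in [0, 1]",
           call. = FALSE)
    }
    structure(list(mode = "constant", s0 = value),
              class = "initial_susceptibility")
  } else {
    if (!is.data.frame(table) || !"s" %in% names(table)) {
      stop("`table` must be a data frame with degree columns and a column `s`",
           call. = FALSE)
    }
    if (any(table$s < 0 | table$s > 1)) {
      stop("all susceptibility values must lie in [0, 1]", call. = FALSE)
    }
    kcols <- setdiff(names(table), "s")
    structure(list(mode = "per_degree",
                   table = table, k_cols = kcols),
              class = "initial_susceptibility")
  }
}

# resolve an s0 argument: numbers are promoted to constant mode
as_s0 <- function(s0) {
  if (inherits(s0, "initial_susceptibility")) return(s0)
  if (is.numeric(s0) && length(s0) == 1) return(initial_susceptibility(s0))
  stop("`s0` must be a number in [0, 1] or an initial_susceptibility object",
       call. = FALSE)
}

# look up s_{(k1,...,kn)} for rows of a joint-degree matrix
s0_lookup <- function(s0, kmat) {
  if (s0$mode == "constant") return(rep(s0$s0, nrow(kmat)))
  key <- apply(kmat, 1, paste, collapse = ",")
  tab_key <- apply(as.matrix(s0$table[s0$k_cols]), 1, paste, collapse = ",")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    stop(sprintf("initial susceptibility table is missing joint degrees: %s",
                 paste(utils::head(key[is.na(idx)], 5), collapse = "; ")),
         call. = FALSE)
  }
  s0$table$s[idx]
}

# mean initial susceptibility E[s(0)]: pmf-weighted for per-degree tables
mean_s0 <- function(e, s0) {
  s0 <- as_s0(s0)
  if (s0$mode == "constant") return(s0$s0)
  jp <- joint_pmf(e)
  sum(jp$prob * s0_lookup(s0, jp$support))
}
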