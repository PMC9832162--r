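#' Sample a multilayer configuration-model graph
#'
#' Draws, independently for each layer, vertex degrees i.i.d. from the
#' layer's pmf and matches stubs uniformly at random. An odd stub total is
#' fixed by redrawing one random vertex's degree. Matchings containing
#' self-loops or duplicate edges are retried up to `max_retries` times; if
#' still imperfect, offending pairs are erased (simple-graph target) and the
#' erased count is reported via a warning and the `erased` attribute.
#'
#' @param e A [network_ensemble()] (transmissibilities unused here).
#' @param N Number of vertices (>= 2).
#' @param seed Optional integer seed; identical seeds give identical graphs.
#' @param max_retries Rematching attempts per layer before erasing.
#' @param erase If `FALSE`, fail instead of erasing after retries.
#' @return A [multilayer_graph()] with attribute `erased` (edges dropped per
#'   layer).
#' @export
sample_multilayer_graph <- function(e, N, seed = NULL, max_retries = 50,
                                    erase = TRUE) {
  stopifnot(inherits(e, "network_ensemble"), N >= 2)
  if (!is.null(seed)) set.seed(seed)
  all_edges <- NULL
  erased <- integer(e$n)
  for (i in seq_len(e$n)) {
    d <- e$layers[[i]]
    deg <- sample(d$degrees, N, replace = TRUE, prob = d$pmf)
    parity_tries <- 0L
    while (sum(deg) %% 2 == 1) {
      parity_tries <- parity_tries + 1L
      if (parity_tries > 1000L) {
        stop(sprintf(
          "layer %d: cannot reach an even stub total (e.g. odd-regular degrees with odd N)",
          i), call. = FALSE)
      }
      deg[sample.int(N, 1)] <- sample(d$degrees, 1, prob = d$pmf)
    }
    edges <- match_stubs(deg, max_retries, erase, layer = i)
    erased[i] <- attr(edges, "erased")
    if (nrow(edges)) {
      all_edges <- rbind(all_edges,
                         data.frame(layer = i, u = edges[, 1] - 1L,
                                    v = edges[, 2] - 1L))
    }
  }
  g <- multilayer_graph(all_edges, n_layers = e$n, N = N)
  attr(g, "erased") <- erased
  g
}

# uniform stub matching for one degree sequence; returns a 2-column matrix of
# 1-based simple edges
match_stubs <- function(deg, max_retries, erase, layer) {
  stubs <- rep(seq_along(deg), deg)
  n_edge <- length(stubs) / 2
  if (n_edge == 0) {
    out <- matrix(integer(0), 0, 2)
    attr(out, "erased") <- 0L
    return(out)
  }
  nv <- length(deg)
  for (attempt in seq_len(max_retries)) {
    perm <- sample(stubs)
    u <- perm[seq_len(n_edge)]
    v <- perm[n_edge + seq_len(n_edge)]
    a <- pmin(u, v); b <- pmax(u, v)
    bad <- a == b | duplicated(a * (nv + 1) + b)
    if (!any(bad)) {
      out <- cbind(a, b)
      attr(out, "erased") <- 0L
      return(out)
    }
    # a clean rematch is hopeless when many pairs clash; fall through to
    # erasure rather than burning the retry budget
    if (sum(bad) > 16 && erase) break
  }
  if (!erase) {
    stop(sprintf(
      "layer %d: no simple stub matching found in %d attempts (erasure disabled)",
      layer, max_retries), call. = FALSE)
  }
  warning(sprintf("layer %d: erased %d self-loop/duplicate edge(s)",
                  layer, sum(bad)), call. = FALSE)
  out <- cbind(a, b)[!bad, , drop = FALSE]
  attr(out, "erased") <- sum(bad)
  out
}

#' Bond percolation on an explicit multilayer graph
#'
#' Opens each layer-`i` edge independently with probability `T_i` and marks
#' as "infected" every vertex reachable from the seed set through open edges.
#' `mode = "mc"` estimates per-vertex infection probabilities and the
#' final-size distribution over `reps` replicates; `mode = "exhaustive"` sums
#' reachability over all `2^E` edge-occupancy states with their exact
#' probabilities (graphs of at most 20 edges).
#'
#' @param g A [multilayer_graph()].
#' @param T Numeric vector of per-layer open probabilities in `[0, 1]`.
#' @param seeds Integer vector of 0-based seed vertices, or `"random"` to
#'   draw one uniform seed per Monte Carlo replicate.
#' @param reps Number of Monte Carlo replicates.
#' @param mode `"mc"` or `"exhaustive"`.
#' @param seed Optional RNG seed.
#' @return Object of class `simulation_result`: list with `p_infected`
#'   (per-vertex probability of ever being infected, seeds included),
#'   `se` (standard errors; 0 in exhaustive mode), `final_sizes` (per
#'   replicate fractions; `NULL` in exhaustive mode), `mean_final_size`,
#'   `reps`, `mode`, `seed`.
#' @export
bond_percolation <- function(g, T, seeds = 0L, reps = 1000,
                             mode = c("mc", "exhaustive"), seed = NULL) {
  stopifnot(inherits(g, "multilayer_graph"))
  mode <- match.arg(mode)
  if (length(T) != g$n || any(T < 0 | T > 1)) {
    stop("`T` must give one probability in [0, 1] per layer", call. = FALSE)
  }
  E <- nrow(g$edges)
  p_edge <- T[g$edges$layer]

  if (mode == "exhaustive") {
    if (identical(seeds, "random")) {
      stop("exhaustive mode requires a fixed seed set", call. = FALSE)
    }
    if (E > 20) {
      stop(sprintf("exhaustive mode supports at most 20 edges (graph has %d)",
                   E), call. = FALSE)
    }
    p_inf <- numeric(g$N)
    mean_size <- 0
    for (mask in 0:(2^E - 1)) {
      open <- bitwAnd(mask, bitwShiftL(1L, seq_len(E) - 1L)) != 0L
      pr <- prod(ifelse(open, p_edge, 1 - p_edge))
      if (pr == 0) next
      reach <- reach_set(g, open, seeds + 1L)
      p_inf[reach] <- p_inf[reach] + pr
      mean_size <- mean_size + pr * length(reach) / g$N
    }
    return(structure(list(p_infected = p_inf, se = numeric(g$N),
                          final_sizes = NULL, mean_final_size = mean_size,
                          reps = NA_integer_, mode = mode, seed = seed),
                     class = "simulation_result"))
  }

  if (!is.null(seed)) set.seed(seed)
  inf_count <- numeric(g$N)
  sizes <- numeric(reps)
  ig <- igraph::make_empty_graph(g$N, directed = FALSE)
  for (r in seq_len(reps)) {
    open <- stats::runif(E) < p_edge
    sub <- igraph::add_edges(ig, t(as.matrix(g$edges[open, c("u", "v")])) + 1L)
    comp <- igraph::components(sub)
    sd_r <- if (identical(seeds, "random")) sample.int(g$N, 1) else seeds + 1L
    reach <- which(comp$membership %in% unique(comp$membership[sd_r]))
    inf_count[reach] <- inf_count[reach] + 1
    sizes[r] <- length(reach) / g$N
  }
  p <- inf_count / reps
  structure(list(p_infected = p, se = sqrt(p * (1 - p) / reps),
                 final_sizes = sizes, mean_final_size = mean(sizes),
                 reps = reps, mode = mode, seed = seed),
            class = "simulation_result")
}

# BFS over open edges; seeds and result are 1-based
reach_set <- function(g, open, seeds1) {
  eo <- g$edges[open, , drop = FALSE]
  adj <- split(c(eo$v, eo$u) + 1L,
               factor(c(eo$u, eo$v) + 1L, levels = seq_len(g$N)))
  visited <- logical(g$N)
  visited[seeds1] <- TRUE
  frontier <- seeds1
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  which(visited)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %s>\n", x$mode))
  cat(sprintf("  mean final size %.6g", x$mean_final_size))
  if (!is.na(x$reps)) cat(sprintf(" over %d replicates", x$reps))
  cat("\n")
  invisible(x)
}

#' Event-driven stochastic SIR on a multilayer graph
#'
#' Exact Gillespie simulation of the continuous-time SIR process: an
#' infectious vertex transmits along each layer-`i` edge to a susceptible
#' neighbour at rate `beta_i` and recovers at rate `gamma`. Along a single
#' isolated edge the neighbour is ever infected with probability
#' `beta_i / (beta_i + gamma)`; this per-edge transmission probability
#' differs from the `T_i = beta_i / gamma` implied by the deterministic
#' models, see [match_transmissibility()] for rate matching.
#'
#' @param g A [multilayer_graph()].
#' @param params [sir_params()].
#' @param initial_infected Integer vector of 0-based initially infectious
#'   vertices, or `"random"` for one uniform vertex per replicate.
#' @param reps Number of replicates.
#' @param seed Optional RNG seed; fixing it fixes the event sequence.
#' @param t_end Stop time (default: run to extinction).
#' @return Object of class `simulation_result` with `p_infected` (fraction
#'   of replicates in which each vertex was ever infected), `se`,
#'   `final_sizes` (fraction ever infected per replicate), `mean_final_size`,
#'   `reps`, `seed`.
#' @export
gillespie_sir <- function(g, params, initial_infected = 0L, reps = 1,
                          seed = NULL, t_end = Inf) {
  stopifnot(inherits(g, "multilayer_graph"), inherits(params, "sir_params"))
  if (length(params$beta) != g$n) {
    stop("`beta` must have one rate per layer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- g$N
  beta <- params$beta
  gamma <- params$gamma
  ever_count <- numeric(N)
  sizes <- numeric(reps)
  for (rep_i in seq_len(reps)) {
    init <- if (identical(initial_infected, "random")) {
      sample.int(N, 1)
    } else {
      initial_infected + 1L
    }
    res <- gillespie_once(g, beta, gamma, init, t_end)
    ever_count <- ever_count + res$ever
    sizes[rep_i] <- sum(res$ever) / N
  }
  p <- ever_count / reps
  structure(list(p_infected = p, se = sqrt(p * (1 - p) / reps),
                 final_sizes = sizes, mean_final_size = mean(sizes),
                 reps = reps, mode = "gillespie", seed = seed),
            class = "simulation_result")
}

gillespie_once <- function(g, beta, gamma, init, t_end) {
  N <- g$N
  n <- g$n
  # status: 0 susceptible, 1 infectious, 2 removed
  status <- integer(N)
  status[init] <- 1L
  # cntS[i, v]: susceptible neighbours of v in layer i
  cntS <- g$degrees
  for (w in init) {
    for (i in seq_len(n)) {
      nb <- g$adj_list[[i]][[w]]
      cntS[i, nb] <- cntS[i, nb] - 1L
    }
  }
  infected <- init
  rate <- numeric(N)  # per-vertex transmission rate, nonzero for infectious
  rate[infected] <- as.numeric(beta %*% cntS[, infected, drop = FALSE])
  t <- 0
  while (length(infected)) {
    tot_inf <- sum(rate[infected])
    tot <- tot_inf + gamma * length(infected)
    t <- t + stats::rexp(1, tot)
    if (t > t_end) break
    if (stats::runif(1) * tot < tot_inf) {
      # transmission: pick infector, then layer, then susceptible neighbour
      v <- if (length(infected) == 1) infected else {
        infected[sample.int(length(infected), 1, prob = rate[infected])]
      }
      layer_w <- beta * cntS[, v]
      i <- if (n == 1) 1L else sample.int(n, 1, prob = layer_w)
      nb <- g$adj_list[[i]][[v]]
      sus <- nb[status[nb] == 0L]
      w <- if (length(sus) == 1) sus else sus[sample.int(length(sus), 1)]
      status[w] <- 1L
      for (j in seq_len(n)) {
        nbw <- g$adj_list[[j]][[w]]
        if (length(nbw)) {
          cntS[j, nbw] <- cntS[j, nbw] - 1L
          inf_nb <- nbw[status[nbw] == 1L]
          # clamp: repeated subtraction can leave -eps when the count hits 0
          rate[inf_nb] <- pmax(rate[inf_nb] - beta[j], 0)
        }
      }
      rate[w] <- as.numeric(beta %*% cntS[, w])
      infected <- c(infected, w)
    } else {
      # recovery
      idx <- if (length(infected) == 1) 1L else {
        sample.int(length(infected), 1)
      }
      v <- infected[idx]
      status[v] <- 2L
      rate[v] <- 0
      infected <- infected[-idx]
    }
  }
  list(ever = status != 0L, t = t)
}

#' Match stochastic rates to a target per-edge transmissibility
#'
#' Returns the transmission rate `beta` such that the event-driven SIR's
#' per-edge transmission probability `beta / (beta + gamma)` equals the
#' target `T`, i.e. `beta = gamma T / (1 - T)`. Use this when comparing the
#' stochastic simulation against percolation or the deterministic mean-field
#' models, whose natural transmissibility is `T = beta / gamma`.
#'
#' @param T Target per-edge transmissibilities in `[0, 1)`.
#' @param gamma Recovery rate.
#' @return Numeric vector of matched rates.
#' @export
match_transmissibility <- function(T, gamma) {
  if (any(T < 0 | T >= 1)) stop("`T` must lie in [0, 1)", call. = FALSE)
  gamma * T / (1 - T)
}
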