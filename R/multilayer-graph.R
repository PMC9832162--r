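#' Explicit multilayer graphs
#'
#' An undirected graph on `N` vertices whose edges are partitioned into `n`
#' layers (edge types). Self-loops are rejected; duplicate edges within a
#' layer are collapsed. Edges are stored once with `u < v` (0-based vertex
#' ids, as in the on-disk edge-list format).
#'
#' @param edges Data frame (or matrix) with columns `layer`, `u`, `v`:
#'   1-based layer indices and 0-based integer vertex ids.
#' @param n_layers Number of layers (defaults to the largest layer index).
#' @param N Number of vertices (defaults to the largest id + 1).
#' @return An object of class `multilayer_graph`: list with `N`, `n`,
#'   `edges` (canonicalised data frame), `degrees` (`n x N` matrix),
#'   `adjacency` (list of `N x N` sparse matrices, one per layer) and
#'   `adj_list` (per layer, per vertex neighbour lists).
#' @export
multilayer_graph <- function(edges, n_layers = NULL, N = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("layer", "u", "v") %in% names(edges))) {
    names(edges)[1:3] <- c("layer", "u", "v")
  }
  for (col in c("layer", "u", "v")) {
    val <- edges[[col]]
    if (!is.numeric(val) || any(val != round(val))) {
      stop(sprintf("column `%s` must contain integers", col), call. = FALSE)
    }
  }
  loops <- which(edges$u == edges$v)
  if (length(loops)) {
    stop(sprintf("self-loop in edge row(s): %s",
                 paste(utils::head(loops, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (any(edges$u < 0 | edges$v < 0)) {
    stop("vertex ids must be nonnegative (0-based)", call. = FALSE)
  }
  if (any(edges$layer < 1)) stop("layer indices are 1-based", call. = FALSE)
  u <- pmin(edges$u, edges$v)
  v <- pmax(edges$u, edges$v)
  can <- data.frame(layer = edges$layer, u = u, v = v)
  can <- unique(can)
  can <- can[order(can$layer, can$u, can$v), , drop = FALSE]
  rownames(can) <- NULL
  n <- if (is.null(n_layers)) max(can$layer) else n_layers
  N <- if (is.null(N)) max(can$v) + 1L else as.integer(N)
  if (max(can$v) + 1L > N) stop("vertex id exceeds N - 1", call. = FALSE)

  adjacency <- vector("list", n)
  adj_list <- vector("list", n)
  degrees <- matrix(0L, n, N)
  for (i in seq_len(n)) {
    ei <- can[can$layer == i, , drop = FALSE]
    A <- Matrix::sparseMatrix(i = c(ei$u, ei$v) + 1L,
                              j = c(ei$v, ei$u) + 1L,
                              x = 1, dims = c(N, N))
    adjacency[[i]] <- A
    degrees[i, ] <- as.integer(Matrix::rowSums(A))
    al <- vector("list", N)
    if (nrow(ei)) {
      pairs <- data.frame(a = c(ei$u, ei$v) + 1L, b = c(ei$v, ei$u) + 1L)
      sp <- split(pairs$b, factor(pairs$a, levels = seq_len(N)))
      al <- lapply(sp, as.integer)
    } else {
      al <- rep(list(integer(0)), N)
    }
    adj_list[[i]] <- al
  }
  structure(list(N = N, n = n, edges = can, degrees = degrees,
                 adjacency = adjacency, adj_list = adj_list),
            class = "multilayer_graph")
}

#' @export
print.multilayer_graph <- function(x, ...) {
  cat(sprintf("<multilayer_graph: %d vertices, %d layer%s, %d edges>\n",
              x$N, x$n, if (x$n > 1) "s" else "", nrow(x$edges)))
  for (i in seq_len(x$n)) {
    cat(sprintf("  layer %d: %d edges, mean degree %.4g\n", i,
                sum(x$edges$layer == i), mean(x$degrees[i, ])))
  }
  invisible(x)
}

#' Read a layered edge list from a TSV file
#'
#' Each row is `layer <TAB> u <TAB> v` with 1-based layer index and 0-based
#' integer vertex ids. Duplicate rows are collapsed; self-loops are rejected
#' with their row number.
#'
#' @param path Path to the TSV file (a header row `layer u v` is optional).
#' @param n_layers,N Optional overrides as in [multilayer_graph()].
#' @return A [multilayer_graph()].
#' @export
read_edge_list <- function(path, n_layers = NULL, N = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("layer", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          col.names = c("layer", "u", "v"),
                          colClasses = "numeric")
  bad <- which(df$layer != round(df$layer) | df$u != round(df$u) |
                 df$v != round(df$v))
  if (length(bad)) {
    stop(sprintf("non-integer ids in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  multilayer_graph(df, n_layers = n_layers, N = N)
}

#' Write a layered edge list to a TSV file
#'
#' @param g A [multilayer_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "multilayer_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
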