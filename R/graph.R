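#' Weighted directed influence network
#'
#' Wraps an `N x N` non-negative weight matrix `M`, where `M[j, i]` scales
#' the influence of node `j`'s state on node `i` (row = source, column =
#' target).  Derived statistics: in-weight `w_in[i] = sum_j M[j, i]`,
#' out-weight `w_out[j] = sum_i M[j, i]`, total weight `m`, and the average
#' weighted degree `w_av = m / N`, the macroscopic topology statistic that
#' drives the mean-field dynamics.
#'
#' @param M square numeric matrix of non-negative weights.
#' @return object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("weight matrix must be square")
  if (any(!is.finite(M))) stop("weights must be finite")
  if (any(M < 0)) stop("negative weights are not allowed")
  structure(list(N = nrow(M), M = unname(M),
                 w_in = unname(colSums(M)), w_out = unname(rowSums(M)),
                 m = sum(M), w_av = sum(M) / nrow(M)),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat(sprintf("<weighted_digraph> N = %d, edges = %d, m = %.4g, w_av = %.4g\n",
              x$N, sum(x$M > 0), x$m, x$w_av))
  invisible(x)
}

is_weighted_digraph <- function(x) inherits(x, "weighted_digraph")

#' Randomly delete a fraction of the edges
#'
#' Emulates a network becoming less connected: a uniformly random subset of
#' the existing (non-zero) edges is removed and degree statistics are
#' recomputed.  Deterministic for a given seed.
#'
#' @param graph a [weighted_digraph()].
#' @param fraction proportion of edges to delete, in `[0, 1]`.
#' @param seed integer seed.
#' @return a new `weighted_digraph`.
#' @export
remove_links <- function(graph, fraction, seed = 1L) {
  stopifnot(is_weighted_digraph(graph), fraction >= 0, fraction <= 1)
  edges <- which(graph$M > 0)
  n_drop <- round(fraction * length(edges))
  M <- graph$M
  if (n_drop > 0L) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    M[sample(edges, n_drop)] <- 0
  }
  weighted_digraph(M)
}

# save/restore RNG state so seeded helpers do not disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Rescale all weights to hit a target average weighted degree
#'
#' Multiplies every weight by one constant so that `w_av` equals `target`.
#'
#' @param graph a [weighted_digraph()].
#' @param target desired `w_av` (>= 0).
#' @return rescaled `weighted_digraph`.
#' @export
scale_to_average_weight <- function(graph, target) {
  stopifnot(is_weighted_digraph(graph), target >= 0)
  if (graph$m == 0) {
    if (target > 0) stop("cannot scale an edgeless graph to positive w_av")
    return(graph)
  }
  weighted_digraph(graph$M * (target / graph$w_av))
}

#' Read a network from a plain-text file
#'
#' Two formats are supported:
#' * `"edgelist"`: CSV with header `source,target,weight`, 0-based integer
#'   node ids; a row means `M[source, target] = weight` (source influences
#'   target).
#' * `"adjacency"`: square CSV of the weight matrix itself, `(row j,
#'   column i) = M_ji`; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"adjacency"`.
#' @param n_nodes optional node count for edge lists (otherwise inferred
#'   from the largest id).
#' @return a [weighted_digraph()].
#' @export
read_network <- function(path, format = c("edgelist", "adjacency"),
                         n_nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "edgelist") {
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("source", "target", "weight")
    if (!all(need %in% names(df)))
      stop("edge list must have header source,target,weight")
    if (nrow(df) == 0L) stop("edge list has no rows: empty graph")
    bad <- which(!is.finite(df$weight) | df$weight < 0)
    if (length(bad))
      stop("invalid weight at data row ", bad[1])
    if (any(df$source != floor(df$source)) || any(df$target != floor(df$target)))
      stop("node ids must be integers")
    N <- if (is.null(n_nodes)) max(df$source, df$target) + 1L else n_nodes
    M <- matrix(0, N, N)
    M[cbind(df$source + 1L, df$target + 1L)] <- df$weight
    weighted_digraph(M)
  } else {
    M <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
    storage.mode(M) <- "double"
    weighted_digraph(M)
  }
}

#' Write a network to a plain-text file
#'
#' @param graph a [weighted_digraph()].
#' @param path output path.
#' @inheritParams read_network
#' @export
write_network <- function(graph, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    idx <- which(graph$M > 0, arr.ind = TRUE)
    df <- data.frame(source = idx[, 1] - 1L, target = idx[, 2] - 1L,
                     weight = graph$M[idx])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# adjacency matrix, entry (row j, column i) = M_ji", con)
    utils::write.table(graph$M, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
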