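#' Synthetic network recipes
#'
#' Declarative description of a synthetic weighted directed network with a
#' controlled average weighted degree; generation is deterministic per
#' seed.  Families: `"erdos-renyi"` (independent directed edges),
#' `"scale-free"` (preferential attachment, symmetrised),
#' `"k-regular"` (every node has `k` out-edges), and
#' `"geometric-commuter"` (cities in a square, distance-decaying weights).
#'
#' @param family network family.
#' @param N node count (>= 1).
#' @param density edge probability (erdos-renyi).
#' @param k out-degree (k-regular) or attachment edges (scale-free) or
#'   nearest-neighbour links (geometric-commuter).
#' @param weight `"constant"` or `"uniform"` edge-weight law.
#' @param w_const constant weight value.
#' @param w_range range of the uniform weight law.
#' @param target_w_av if non-`NULL`, globally rescale to this average
#'   weighted degree.
#' @param box_size,beta geometric-commuter box side and distance-decay
#'   exponent.
#' @param seed integer seed.
#' @return object of class `network_recipe`.
#' @export
network_recipe <- function(family = c("erdos-renyi", "scale-free",
                                      "k-regular", "geometric-commuter"),
                           N, density = 0.1, k = 4L,
                           weight = c("constant", "uniform"), w_const = 1,
                           w_range = c(0.5, 1.5), target_w_av = NULL,
                           box_size = 1, beta = 2, seed = 1L) {
  family <- match.arg(family)
  weight <- match.arg(weight)
  if (N < 1) stop("N must be at least 1")
  if (!is.null(target_w_av) && target_w_av < 0) stop("target_w_av must be >= 0")
  structure(as.list(environment()), class = "network_recipe")
}

#' Generate a synthetic network from a recipe
#'
#' @param recipe a [network_recipe()].
#' @return a [weighted_digraph()] (for `"geometric-commuter"`, with the
#'   distance matrix attached as attribute `"distances"`).
#' @export
generate_network <- function(recipe) {
  stopifnot(inherits(recipe, "network_recipe"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(recipe$seed)
  N <- as.integer(recipe$N)
  draw_w <- function(n) switch(recipe$weight,
    constant = rep(recipe$w_const, n),
    uniform  = stats::runif(n, recipe$w_range[1], recipe$w_range[2]))
  M <- switch(recipe$family,
    "erdos-renyi" = {
      A <- matrix(stats::runif(N * N) < recipe$density, N, N)
      diag(A) <- FALSE
      M <- matrix(0, N, N)
      M[A] <- draw_w(sum(A))
      M
    },
    "k-regular" = {
      if (recipe$k >= N) stop("k must be smaller than N")
      M <- matrix(0, N, N)
      for (j in seq_len(N)) {
        targets <- sample(setdiff(seq_len(N), j), recipe$k)
        M[j, targets] <- draw_w(recipe$k)
      }
      M
    },
    "scale-free" = {
      m0 <- max(2L, recipe$k)
      if (N <= m0) stop("N must exceed the attachment parameter")
      adj <- matrix(FALSE, N, N)
      adj[seq_len(m0), seq_len(m0)] <- TRUE
      diag(adj) <- FALSE
      deg <- rowSums(adj) + colSums(adj)
      for (v in (m0 + 1L):N) {
        prev <- seq_len(v - 1L)
        pick <- sample(prev, min(recipe$k, v - 1L),
                       prob = deg[prev] + 1)
        adj[v, pick] <- TRUE
        adj[pick, v] <- TRUE
        deg[pick] <- deg[pick] + 2
        deg[v] <- deg[v] + 2 * length(pick)
      }
      M <- matrix(0, N, N)
      up <- which(adj & upper.tri(adj))
      w <- draw_w(length(up))
      M[up] <- w
      tM <- t(M); M[lower.tri(M)] <- tM[lower.tri(M)]
      M
    },
    "geometric-commuter" = {
      return(generate_commuter_network(N, recipe$box_size, recipe$beta,
                                       recipe$seed, k = recipe$k,
                                       target_w_av = recipe$target_w_av)$graph)
    })
  g <- weighted_digraph(M)
  if (!is.null(recipe$target_w_av)) g <- scale_to_average_weight(g, recipe$target_w_av)
  g
}

#' Synthetic commuter network on a square
#'
#' Cities placed uniformly at random in a `box_size x box_size` square;
#' each city is linked (symmetrically) to its `k` nearest neighbours with
#' service weight `exp(-d^beta)`, decreasing in distance.
#'
#' @param N number of cities (>= 2).
#' @param box_size square side length.
#' @param beta distance-decay exponent.
#' @param seed integer seed.
#' @param k nearest-neighbour links per city.
#' @param target_w_av optional global rescale of the weights.
#' @return list with `graph` (a [weighted_digraph()], distances attached
#'   as attribute) and `distances` (symmetric matrix, zero diagonal).
#' @export
generate_commuter_network <- function(N, box_size = 1, beta = 2, seed = 1L,
                                      k = 4L, target_w_av = NULL) {
  stopifnot(N >= 2)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  xy <- matrix(stats::runif(2L * N, 0, box_size), ncol = 2L)
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- NULL
  M <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- order(d[i, ])[2:(min(k, N - 1L) + 1L)]
    M[i, nb] <- exp(-d[i, nb]^beta)
    M[nb, i] <- exp(-d[nb, i]^beta)
  }
  g <- weighted_digraph(M)
  if (!is.null(target_w_av)) g <- scale_to_average_weight(g, target_w_av)
  attr(g, "distances") <- d
  list(graph = g, distances = d)
}

#' Sweep network-level resilience over average weight
#'
#' For each grid value of the average weighted degree the graph is
#' rescaled, the deterministic mean-field indicator is computed
#' (probability = 1 if \eqn{\tau > 0}, else 0), and -- when `inputs` are
#' given -- the uncertain resilience probability is added: in `"shared"`
#' mode via an aPC surrogate of the network indicator over the inputs, in
#' `"iid"` mode via the CLT reduction and a Hermite PCE of
#' \eqn{\tau(\zeta)}.
#'
#' @param model a [dynamics_model()].
#' @param graph a [weighted_digraph()] (topology; rescaled per grid point).
#' @param w_av_grid grid of average weights.
#' @param inputs optional named list of [random_input()]s.
#' @param mode `"shared"` or `"iid"` (used when `inputs` given).
#' @param order surrogate truncation order.
#' @param n_samples surrogate sampling size for shared mode.
#' @param seed RNG seed.
#' @return data frame: one row per (grid point x method) with columns
#'   `w_av, target, method, tau, probability, order, seed`.
#' @export
sweep_network_resilience <- function(model, graph, w_av_grid, inputs = NULL,
                                     mode = c("shared", "iid"), order = 3L,
                                     n_samples = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  rows <- list()
  for (w in w_av_grid) {
    gw <- scale_to_average_weight(graph, w)
    tau_det <- resilience_indicator(effective_rhs(model, gw))$tau
    rows[[length(rows) + 1L]] <- data.frame(
      w_av = w, target = "network", method = "deterministic",
      tau = tau_det, probability = as.numeric(tau_det > 0),
      order = NA_integer_, seed = seed)
    if (!is.null(inputs)) {
      if (mode == "iid") {
        md <- model; md$params[names(inputs)] <- inputs
        st <- clt_statistics(md)
        sur <- fit_tau_pce(st, gw, order = order)
        pr <- network_resilience_probability(sur)
      } else {
        tau_fn <- function(xi) tau_eff_batch(model, w, xi)$tau
        sur <- fit_apc_surrogate(tau_fn, inputs, order, seed = seed)
        old <- .Random.seed_get()
        set.seed(seed)
        pts <- vapply(inputs, ri_sample, numeric(n_samples), n = n_samples)
        pr <- list(value = mean(predict(sur, pts) > 0))
        .Random.seed_set(old)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        w_av = w, target = "network", method = paste0("uncertain-", mode),
        tau = NA_real_, probability = pr$value, order = order, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Order/accuracy comparison of aPC against the Monte Carlo baseline
#'
#' Runs the node-level aPC surrogate for a ladder of truncation orders and
#' the direct Monte Carlo estimator for a ladder of sample sizes; the
#' large-sample Monte Carlo run is the reference.  Accuracy is reported as
#' `1 - |p - p_ref| / p_ref` and cost as model-evaluation counts
#' (hardware-independent, unlike wall-clock time).
#'
#' @inheritParams fit_node_apc
#' @param orders aPC truncation orders to try.
#' @param mc_sizes Monte Carlo sample-size ladder.
#' @param n_ref reference Monte Carlo sample count (>= max(mc_sizes)).
#' @param n_prob surrogate sampling size for the probability integral.
#' @param seed RNG seed.
#' @return data frame with columns `node, method, order, n_samples,
#'   n_evals, probability, accuracy, seed`.
#' @export
order_accuracy_report <- function(model, graph, node, inputs = NULL,
                                  orders = 1:4,
                                  mc_sizes = c(50L, 100L, 400L, 1000L),
                                  n_ref = 2000L, n_prob = 1e5, seed = 1L) {
  if (is.null(inputs)) inputs <- model$params[uncertain_names(model)]
  stopifnot(n_ref >= max(mc_sizes))
  ref <- mc_node_probability(model, graph, node, inputs, n_samples = n_ref,
                             seed = seed + 999L)
  acc <- function(p) 1 - abs(p - ref$probability) / ref$probability
  rows <- list()
  for (r in orders) {
    sur <- fit_node_apc(model, graph, node, inputs, order = r, seed = seed)
    rep_ <- node_resilience_probability(sur, inputs, n_samples = n_prob,
                                        seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, method = "apc", order = r, n_samples = n_prob,
      n_evals = sur$n_design, probability = rep_$probability,
      accuracy = acc(rep_$probability), seed = seed)
  }
  for (n in mc_sizes) {
    rep_ <- mc_node_probability(model, graph, node, inputs, n_samples = n,
                                seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, method = "mc", order = NA_integer_, n_samples = n,
      n_evals = n, probability = rep_$probability,
      accuracy = acc(rep_$probability), seed = seed)
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref
  out
}

#' Read an uncertainty specification file
#'
#' JSON file mapping parameter names to blocks with `kind` and `params`
#' (for named distributions), or `samples_file` (one value per line), or
#' `moments` (raw moment list starting at \eqn{\mu_0}).
#'
#' @param path JSON file path.
#' @return named list of [random_input()]s.
#' @export
read_uncertainty <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(spec), function(nm) {
    blk <- spec[[nm]]
    if (!is.null(blk$samples_file)) {
      sf <- blk$samples_file
      if (!file.exists(sf))
        sf <- file.path(dirname(path), blk$samples_file)
      random_input("samples", x = scan(sf, quiet = TRUE), label = nm)
    } else if (!is.null(blk$moments)) {
      random_input("moments", mu = unlist(blk$moments), label = nm)
    } else {
      do.call(random_input,
              c(list(kind = blk$kind, label = nm), as.list(blk$params)))
    }
  })
  names(out) <- names(spec)
  out
}

#' Write a results table
#'
#' CSV or JSON; JSON output echoes the configuration for reproducibility.
#'
#' @param table data frame of results.
#' @param path output path (`.csv` or `.json`).
#' @param config optional configuration list echoed into JSON output.
#' @export
write_results <- function(table, path, config = NULL) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(config = config, results = table), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
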