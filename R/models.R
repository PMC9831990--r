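#' Networked nonlinear dynamics models
#'
#' A `dynamics_model` pairs a self-dynamics function `f(x, p)` with a
#' pairwise coupling function `g(xi, xj, p)`; node `i` of a network then
#' evolves as \deqn{\dot x_i = f(x_i, a) + \sum_j M_{ji}\, g(x_i, x_j, b).}
#' Parameters live in a named list `params`; any entry may be a plain number
#' (certain) or a [random_input()] (uncertain).  `a_names` / `b_names`
#' declare which parameters feed `f` and `g`.  The uncertainty mode is
#' either `"shared"` (one draw used by every node) or `"iid"` (an
#' independent draw per node, the regime in which the central-limit network
#' reduction is valid).
#'
#' @param name model label.
#' @param f function of `(x, p)`, vectorised in `x`.
#' @param g function of `(xi, xj, p)`, vectorised elementwise.
#' @param params named list of parameter values and/or [random_input()]s.
#' @param a_names,b_names parameter names used by `f` resp. `g`.
#' @param x_max_fn function of resolved parameters giving the state-scan
#'   upper bound (default twice the carrying capacity).
#' @param mode `"shared"` or `"iid"` uncertainty mode.
#' @param coupling_full optional function `(x, graph, p)` returning the full
#'   coupling vector for models whose interaction is not a pairwise sum
#'   (competitive commuter dynamics).
#' @param domain_min states below this are rejected (`-Inf` to disable).
#' @return object of class `dynamics_model`.
#' @export
dynamics_model <- function(name, f, g, params, a_names, b_names,
                           x_max_fn, mode = c("shared", "iid"),
                           coupling_full = NULL, domain_min = -Inf) {
  mode <- match.arg(mode)
  stopifnot(is.function(f), is.function(g), is.list(params))
  if (length(unc <- uncertain_names_(params)) > 10L)
    stop("at most 10 uncertain parameters are supported")
  structure(list(name = name, f = f, g = g, params = params,
                 a_names = a_names, b_names = b_names,
                 x_max_fn = x_max_fn, mode = mode,
                 coupling_full = coupling_full, domain_min = domain_min),
            class = "dynamics_model")
}

uncertain_names_ <- function(params)
  names(params)[vapply(params, is_random_input, TRUE)]

#' Names of the uncertain parameters of a model
#' @param model a [dynamics_model()].
#' @return character vector (possibly empty).
#' @export
uncertain_names <- function(model) uncertain_names_(model$params)

#' Resolve model parameters at a realization
#'
#' Certain parameters pass through; uncertain ones take their value from
#' `realization` (a named list/vector), or their distribution mean when
#' `realization` is `NULL` or omits them.  Entries may be scalars (shared
#' across nodes) or length-`N` vectors (iid-per-node draws).
#'
#' @param model a [dynamics_model()].
#' @param realization named list or vector of values for uncertain
#'   parameters, or `NULL` for the mean point.
#' @return named list of numeric parameter values.
#' @export
resolve_params <- function(model, realization = NULL) {
  p <- model$params
  for (nm in names(p)) {
    if (is_random_input(p[[nm]])) {
      if (!is.null(realization) && nm %in% names(realization))
        p[[nm]] <- as.numeric(realization[[nm]])
      else
        p[[nm]] <- ri_mean(p[[nm]])
    }
  }
  p
}

#' Mutualistic pollinator dynamics
#'
#' Species abundance \eqn{x_i} with incoming migration `B`, logistic growth
#' with carrying capacity `K`, an Allee threshold `C` (growth is negative
#' below `C`), and a saturating mutualistic coupling:
#' \deqn{\dot x_i = B + x_i(1 - x_i/K)(x_i/C - 1)
#'   + \sum_j M_{ji} \frac{x_i x_j}{D + E x_i + H x_j}.}
#' Defaults are the homogeneous values used throughout the case study:
#' `B = 0.1, C = 1, K = 5, D = 5, E = 0.9, H = 0.1`.
#'
#' @param B,C,K,D,E,H parameter values; each may be a number or a
#'   [random_input()].
#' @param mode uncertainty mode, see [dynamics_model()].
#' @return a `dynamics_model`.
#' @examples
#' mod <- mutualistic_model()
#' g <- weighted_digraph(matrix(0, 2, 2))
#' full_rhs(mod, g, c(0, 0))  # migration only: 0.1, 0.1
#' @export
mutualistic_model <- function(B = 0.1, C = 1, K = 5, D = 5, E = 0.9, H = 0.1,
                              mode = c("shared", "iid")) {
  dynamics_model(
    name = "mutualistic",
    f = function(x, p) p$B + x * (1 - x / p$K) * (x / p$C - 1),
    g = function(xi, xj, p) xi * xj / (p$D + p$E * xi + p$H * xj),
    params = list(B = B, C = C, K = K, D = D, E = E, H = H),
    a_names = c("B", "C", "K"), b_names = c("D", "E", "H"),
    x_max_fn = function(p) 2 * max(p$K),
    mode = match.arg(mode))
}

#' Generic bistable dynamics with saturating coupling
#'
#' Same bistable self-dynamics family as the mutualistic model (migration +
#' logistic + Allee) with the simplest saturating positive coupling
#' `g(xi, xj) = xj / (1 + xj)`; a minimal test-bed for resilience concepts.
#'
#' @inheritParams mutualistic_model
#' @return a `dynamics_model`.
#' @export
bistable_model <- function(B = 0.1, C = 1, K = 5, mode = c("shared", "iid")) {
  dynamics_model(
    name = "bistable",
    f = function(x, p) p$B + x * (1 - x / p$K) * (x / p$C - 1),
    g = function(xi, xj, p) xj / (1 + xj),
    params = list(B = B, C = C, K = K),
    a_names = c("B", "C", "K"), b_names = character(0),
    x_max_fn = function(p) 2 * max(p$K),
    mode = match.arg(mode))
}

#' Commuter-flow (Boltzmann--Lotka--Volterra) dynamics
#'
#' Worker population \eqn{x_i} of city `i` under logistic growth with
#' transport carrying capacity `K_i`, a job-criticality Allee threshold
#' `C_i`, and competitive commuter inflow over the weighted service network.
#' Two coupling interpretations are provided:
#'
#' * `coupling = "share"`: the inflow from `j` to `i` is `j`'s outflow
#'   `x_j` split competitively across `j`'s receivers,
#'   \eqn{M_{ji} x_j A_i / \sum_k M_{jk} A_k} with attractiveness
#'   \eqn{A_q = \exp[\alpha \log x_q - d_{jq}^\beta]}; each sender's shares
#'   sum to one.
#' * `coupling = "literal"`: the printed formula in which the
#'   attractiveness exponent uses the *receiving* city in both numerator
#'   and denominator (where it then cancels); kept for fidelity, not
#'   recommended.
#'
#' For the mean-field and node-level reductions, which need a pairwise
#' kernel, the share interpretation at a homogeneous competitor state is
#' used: `g(xi, xj) = xi^alpha * xj^(1-alpha) / w_ref`, with the reference
#' total out-weight `w_ref` set to the graph's `w_av` by the reduction
#' code (so that at a uniform state the mean coupling per node is exactly
#' `x`, matching the share construction).
#'
#' @param K,C carrying capacities and criticality thresholds (scalar or
#'   per-node; `K > C > 0`); may be [random_input()]s.
#' @param alpha attractiveness (critical-mass) exponent.
#' @param beta distance-cost exponent.
#' @param distances symmetric `N x N` distance matrix with zero diagonal.
#' @param coupling `"share"` or `"literal"`.
#' @param mode uncertainty mode.
#' @return a `dynamics_model` carrying `distances` and `coupling`.
#' @export
commuter_model <- function(K = 10, C = 1, alpha = 0.5, beta = 2, distances,
                           coupling = c("share", "literal"),
                           mode = c("shared", "iid")) {
  coupling <- match.arg(coupling)
  d <- as.matrix(distances)
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0))
    stop("distances must be symmetric with zero diagonal")
  if (any(d[upper.tri(d)] <= 0)) stop("off-diagonal distances must be positive")
  kn <- if (is_random_input(K)) ri_mean(K) else K
  cn <- if (is_random_input(C)) ri_mean(C) else C
  if (!all(kn > cn) || !all(cn > 0)) stop("need K > C > 0")
  d_bar <- mean(d[upper.tri(d)])
  mod <- dynamics_model(
    name = "commuter",
    f = function(x, p) x * (1 - x / p$K) * (x / p$C - 1),
    g = function(xi, xj, p) {
      xi <- pmax(xi, 1e-12); xj <- pmax(xj, 1e-12)
      xi^p$alpha * xj^(1 - p$alpha) / p$w_ref
    },
    params = list(K = K, C = C, alpha = alpha, beta = beta, w_ref = 1),
    a_names = c("K", "C"), b_names = c("alpha", "beta", "w_ref"),
    x_max_fn = function(p) 2 * max(p$K),
    mode = match.arg(mode),
    coupling_full = function(x, graph, p) {
      commuter_coupling(x, graph$M, d, p$alpha, p$beta, coupling)
    },
    domain_min = 0)
  mod$distances <- d
  mod$coupling <- coupling
  mod$d_bar <- d_bar
  mod
}

commuter_coupling <- function(x, M, d, alpha, beta, coupling) {
  N <- length(x)
  xs <- pmax(x, 1e-12)
  out <- numeric(N)
  if (coupling == "share") {
    # A[j, q] = exp(alpha*log(x_q) - d_jq^beta)
    A <- exp(-d^beta) * matrix(xs^alpha, N, N, byrow = TRUE)
    denom <- rowSums(M * A)
    ok <- denom > 0
    share <- matrix(0, N, N)
    share[ok, ] <- (M * A)[ok, , drop = FALSE] / denom[ok]
    out <- colSums(share * xs)          # sum_j share_ji * x_j
  } else {
    # literal printed form: receiver's attractiveness everywhere (cancels)
    B <- exp(-d^beta)                   # B[i, q] after x_i^alpha cancels
    for (i in seq_len(N)) {
      num <- M[, i] * xs * B[i, ]
      den <- as.numeric(M %*% (xs * B[i, ]))
      ok <- den > 0 & M[, i] > 0
      out[i] <- sum(num[ok] / den[ok])
    }
  }
  out
}

#' Full networked right-hand side
#'
#' Evaluates \eqn{\dot x_i = f(x_i, a) + \sum_j M_{ji} g(x_i, x_j, b)} for
#' every node, at a given realization of the uncertain parameters.
#'
#' @param model a [dynamics_model()].
#' @param graph a [weighted_digraph()].
#' @param x state vector of length `N`.
#' @param realization see [resolve_params()]; per-node (length-`N`) values
#'   are allowed in `"iid"` mode.
#' @return derivative vector of length `N`.
#' @export
full_rhs <- function(model, graph, x, realization = NULL) {
  stopifnot(is_weighted_digraph(graph), length(x) == graph$N)
  if (any(x < model$domain_min))
    stop("state outside model domain (x < ", model$domain_min, ")")
  p <- resolve_params(model, realization)
  drift <- model$f(x, p)
  if (!is.null(model$coupling_full)) {
    coup <- model$coupling_full(x, graph, p)
  } else {
    lens <- vapply(p[model$b_names], length, 0L)
    if (all(lens <= 1L)) {
      G <- outer(x, x, function(xj, xi) model$g(xi, xj, p))  # G[j, i]
      coup <- colSums(graph$M * G)
    } else {
      # per-node coupling parameters: parameter of the source node j
      coup <- numeric(graph$N)
      for (j in seq_len(graph$N)) {
        pj <- p
        for (nm in model$b_names)
          if (length(pj[[nm]]) > 1L) pj[[nm]] <- pj[[nm]][j]
        coup <- coup + graph$M[j, ] * model$g(x, x[j], pj)
      }
    }
  }
  drift + coup
}

#' Integrate the networked dynamics
#'
#' Adaptive Dormand--Prince Runge--Kutta (order 5(4)) integration of the
#' full system from `x0` over `[0, horizon]`.
#'
#' @inheritParams full_rhs
#' @param x0 initial state.
#' @param horizon final time (> 0).
#' @param rtol,atol relative/absolute local error tolerances.
#' @param n_save number of saved time points (including endpoints).
#' @return list with `times`, `states` (matrix, one row per saved time),
#'   `terminal` (final state), and the tolerances used.
#' @export
simulate_dynamics <- function(model, graph, x0, horizon, realization = NULL,
                              rtol = 1e-8, atol = 1e-10, n_save = 101L) {
  stopifnot(horizon > 0)
  rhs <- function(x) full_rhs(model, graph, x, realization)
  out <- rk45(rhs, x0, horizon, rtol, atol, n_save)
  out$rtol <- rtol; out$atol <- atol
  out
}

# Dormand-Prince 5(4) with step-size control and dense save via interpolation
rk45 <- function(rhs, x0, horizon, rtol, atol, n_save) {
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
            c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  t <- 0; x <- x0; h <- horizon / 100
  save_t <- seq(0, horizon, length.out = n_save)
  times <- numeric(0); states <- list()
  ti <- 1L
  k1 <- rhs(x)
  record <- function(tt, xx) { times <<- c(times, tt); states[[length(states) + 1L]] <<- xx }
  record(0, x0); ti <- 2L
  n_step <- 0L
  while (t < horizon) {
    n_step <- n_step + 1L
    if (n_step > 1e6) stop("integration failed to converge by t = ", t)
    h <- min(h, horizon - t)
    k <- list(k1)
    for (s in 1:6) {
      xi <- x
      for (q in seq_len(s)) xi <- xi + h * a[[s]][q] * k[[q]]
      k[[s + 1L]] <- rhs(xi)
    }
    x5 <- x; x4 <- x
    for (q in 1:7) { x5 <- x5 + h * b5[q] * k[[q]]; x4 <- x4 + h * b4[q] * k[[q]] }
    if (any(!is.finite(x5)) || max(abs(x5)) > 1e10)
      stop("integration blow-up at t = ", signif(t, 6))
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    err <- sqrt(mean(((x5 - x4) / sc)^2))
    if (err <= 1) {
      t_new <- t + h
      while (ti <= n_save && save_t[ti] <= t_new + 1e-14) {
        w <- if (h > 0) (save_t[ti] - t) / h else 0
        record(save_t[ti], x + w * (x5 - x))   # linear dense output
        ti <- ti + 1L
      }
      t <- t_new; x <- x5; k1 <- k[[7]]
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^0.2))
  }
  states <- do.call(rbind, states)
  list(times = times, states = states, terminal = x)
}
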