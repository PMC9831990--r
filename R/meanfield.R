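#' One-dimensional effective (mean-field) dynamics
#'
#' Collapses the N coupled equations to one effective equation
#' \deqn{\Xi(x) = \frac1N \sum_i f(x, a) + \frac1N \sum_{i,j} M_{ji}\,
#'   g(x, x, b),}
#' which for homogeneous parameters reduces to
#' \eqn{f(x) + w_{av}\, g(x, x)}.  Heterogeneous (per-node) parameter
#' values are averaged over the node population numerically; per-node
#' coupling parameters are weighted by out-weight, as the double sum
#' dictates.
#'
#' @param model a [dynamics_model()].
#' @param graph a [weighted_digraph()].
#' @param realization values for uncertain parameters (see
#'   [resolve_params()]); `NULL` for the mean point.
#' @return object of class `effective_dynamics`: callable `fn(x)`
#'   (vectorised), scan bound `x_max`, and provenance.
#' @export
effective_rhs <- function(model, graph, realization = NULL) {
  stopifnot(is_weighted_digraph(graph))
  p <- resolve_params(model, realization)
  if ("w_ref" %in% names(p)) p$w_ref <- graph$w_av
  effective_dynamics_(model, p, graph$w_av, graph = graph)
}

# core constructor; graph only needed for non-pairwise couplings and
# out-weighted averaging of per-node coupling parameters
effective_dynamics_ <- function(model, p, w_av, graph = NULL) {
  a_len <- vapply(p[model$a_names], length, 0L)
  b_len <- if (length(model$b_names))
    vapply(p[model$b_names], length, 0L) else integer(0)
  f_bar <- if (all(a_len <= 1L)) {
    function(x) model$f(x, p)
  } else {
    n_nodes <- max(a_len)
    function(x) {
      acc <- 0
      for (i in seq_len(n_nodes)) {
        pi <- p
        for (nm in model$a_names)
          if (length(pi[[nm]]) > 1L) pi[[nm]] <- pi[[nm]][i]
        acc <- acc + model$f(x, pi)
      }
      acc / n_nodes
    }
  }
  if (!is.null(model$effective_coupling)) {
    c_bar <- model$effective_coupling(graph, p)
  } else if (all(b_len <= 1L)) {
    c_bar <- function(x) w_av * model$g(x, x, p)
  } else {
    if (is.null(graph))
      stop("per-node coupling parameters need an explicit graph")
    w_out <- graph$w_out
    c_bar <- function(x) {
      acc <- 0
      for (j in seq_len(graph$N)) {
        pj <- p
        for (nm in model$b_names)
          if (length(pj[[nm]]) > 1L) pj[[nm]] <- pj[[nm]][j]
        acc <- acc + w_out[j] * model$g(x, x, pj)
      }
      acc / graph$N
    }
  }
  structure(list(fn = function(x) f_bar(x) + c_bar(x),
                 x_max = model$x_max_fn(p),
                 model = model, w_av = w_av, params = p),
            class = "effective_dynamics")
}

# homogeneous effective dynamics at a prescribed average weight
effective_homogeneous <- function(model, w_av, realization = NULL) {
  p <- resolve_params(model, realization)
  if ("w_ref" %in% names(p)) p$w_ref <- w_av
  effective_dynamics_(model, p, w_av)
}

#' Equilibria of a one-dimensional dynamics
#'
#' Scans `[0, x_max]` on a dense grid for sign changes of the right-hand
#' side, refines each by bracketed root finding to \eqn{|\Xi| <
#' 10^{-10}}, and classifies stability by the sign of the derivative.
#'
#' @param eff an `effective_dynamics` (from [effective_rhs()]) or any list
#'   with fields `fn` and `x_max`.
#' @param n_grid scan resolution before refinement.
#' @return data frame with columns `x` and `stable`; zero rows (with a
#'   warning) when no sign change is found.
#' @export
equilibria <- function(eff, n_grid = 2000L) {
  x_hi <- eff$x_max
  k <- 0L  # extend until the bounded-growth tail is negative
  while (eff$fn(x_hi) >= 0 && k < 60L) { x_hi <- x_hi * 1.5; k <- k + 1L }
  grid <- seq(0, x_hi, length.out = n_grid)
  y <- eff$fn(grid)
  sgn <- sign(y)
  cross <- which(sgn[-n_grid] * sgn[-1L] < 0)
  roots <- vapply(cross, function(i)
    stats::uniroot(eff$fn, c(grid[i], grid[i + 1L]),
                   tol = .Machine$double.eps^0.75)$root, 0)
  roots <- c(roots, grid[sgn == 0])
  roots <- sort(unique(roots))
  if (!length(roots)) {
    warning("no equilibrium found on [0, ", signif(eff$x_max, 4), "]")
    return(data.frame(x = numeric(0), stable = logical(0)))
  }
  h <- eff$x_max * 1e-7
  stable <- (eff$fn(roots + h) - eff$fn(pmax(roots - h, 0))) < 0
  data.frame(x = roots, stable = stable)
}

#' Resilience indicator of a one-dimensional dynamics
#'
#' The indicator \eqn{\tau} is the value of the first strict interior local
#' minimum of the right-hand side on \eqn{(0, x_{healthy})}, where
#' \eqn{x_{healthy}} is the largest equilibrium.  \eqn{\tau > 0} means the
#' dip does not touch zero, so only the healthy equilibrium exists and the
#' system is resilient; \eqn{\tau < 0} means a healthy and an unhealthy
#' stable state coexist.  If the right-hand side has no interior dip,
#' \eqn{\tau} is the minimum over the interval and the result is flagged.
#'
#' @inheritParams equilibria
#' @return object of class `resilience_indicator`: `tau`, `x_min`,
#'   `resilient` (`tau > 0`), `monotone` flag, `x_healthy`, `n_stable`.
#' @export
resilience_indicator <- function(eff, n_grid = 2000L) {
  eq <- equilibria(eff, n_grid)
  if (!nrow(eq)) stop("no equilibrium: cannot define a resilience indicator")
  x_healthy <- max(eq$x)
  grid <- seq(0, x_healthy, length.out = n_grid)
  y <- eff$fn(grid)
  mid <- 2:(n_grid - 1L)
  i_min <- mid[y[mid] < y[mid - 1L] & y[mid] <= y[mid + 1L]][1]
  if (is.na(i_min)) {
    # no interior dip: minimum over the OPEN interval (0, x_healthy) -- the
    # endpoints (x = 0 and the healthy root itself, where the rhs is ~0)
    # do not count
    j <- which.min(y[mid]) + 1L
    out <- list(tau = y[j], x_min = grid[j], monotone = TRUE)
  } else {
    opt <- stats::optimize(eff$fn, c(grid[i_min - 1L], grid[i_min + 1L]),
                           tol = 1e-8)
    out <- list(tau = opt$objective, x_min = opt$minimum, monotone = FALSE)
  }
  structure(c(out, list(resilient = out$tau > 0, x_healthy = x_healthy,
                        n_stable = sum(eq$stable))),
            class = "resilience_indicator")
}

#' @export
print.resilience_indicator <- function(x, ...) {
  cat(sprintf("<resilience_indicator> tau = %.6g at x = %.6g (%s)\n",
              x$tau, x$x_min,
              if (x$resilient) "resilient" else "not resilient"))
  invisible(x)
}

#' Healthy equilibrium of the mean-field dynamics
#'
#' Largest non-negative root of the effective dynamics at the given
#' realization: the sequential estimation scheme's first-step neighbour
#' estimate \eqn{x_e^0 = h(\xi_1, \dots, \xi_l)}.
#'
#' @inheritParams effective_rhs
#' @param n_grid scan resolution.
#' @return list: `x_e0`, `multiple` (`TRUE` when an unhealthy stable root
#'   coexists), and the equilibrium table.
#' @export
healthy_equilibrium <- function(model, graph, realization = NULL,
                                n_grid = 2000L) {
  eff <- effective_rhs(model, graph, realization)
  eq <- equilibria(eff, n_grid)
  if (!nrow(eq)) stop("effective dynamics has no root on the scan domain")
  list(x_e0 = max(eq$x), multiple = sum(eq$stable) > 1L, equilibria = eq)
}

#' Saddle-node bifurcation threshold of the average weight
#'
#' Bisects on the average weighted degree for the sign change of the
#' mean-field resilience indicator \eqn{\tau(w_{av})}; the returned
#' \eqn{w_*} is the smallest average weight at which the unhealthy dip
#' lifts above zero, i.e. where the mean-field system undergoes its
#' saddle-node bifurcation.
#'
#' @param model a [dynamics_model()] with deterministic (or mean-resolved)
#'   homogeneous parameters.
#' @param bracket search interval for `w_av`.
#' @param tol bisection bracket width.
#' @param realization optional fixed realization of uncertain parameters.
#' @return list: `w_star`, `bracket` (final), `tau_lo`, `tau_hi`.
#' @export
critical_threshold <- function(model, bracket = c(3, 12), tol = 1e-3,
                               realization = NULL) {
  tau_at <- function(w)
    resilience_indicator(effective_homogeneous(model, w, realization))$tau
  lo <- bracket[1]; hi <- bracket[2]
  t_lo <- tau_at(lo); t_hi <- tau_at(hi)
  if (t_lo * t_hi > 0)
    stop(sprintf("tau does not change sign on [%g, %g] (tau = %.4g, %.4g)",
                 lo, hi, t_lo, t_hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tau_at(mid) * t_lo <= 0) hi <- mid else { lo <- mid; t_lo <- tau_at(lo) }
  }
  list(w_star = (lo + hi) / 2, bracket = c(lo, hi),
       tau_lo = tau_at(lo), tau_hi = tau_at(hi))
}

#' Critical-weight curve: node-level resilience boundary vs average weight
#'
#' For each average weight on the grid, the mean-field equilibrium estimate
#' \eqn{x_e^0(w_{av})} is computed, then the one-node dynamics
#' \eqn{\dot x = f(x) + w^{in} g(x, x_e^0)} is bisected on the in-weight
#' for the sign change of its local-minimum indicator.  `w_crit` is the
#' minimum in-weight a node needs to be resilient; it is recorded as 0
#' when the node is resilient even with no in-weight.
#'
#' \eqn{x_e^0} here is the state the network actually attains: above the
#' bifurcation threshold the unique (healthy) equilibrium, below it the
#' unhealthy one -- a bistable network relaxes to the collapsed state after
#' perturbation, so that is the neighbour state a marginal node sees.  This
#' makes \eqn{x_e^0(w_{av})}, and with it `w_crit`, discontinuous at the
#' threshold \eqn{w_*}: below it a node needs a large in-weight to stay
#' resilient on its own, above it almost none.
#'
#' @param model a [dynamics_model()].
#' @param w_av_grid ascending grid of average weights.
#' @param w_in_max upper bracket for the node in-weight bisection.
#' @param tol bisection width.
#' @param realization optional fixed realization.
#' @return object of class `critical_curve`: data frame `curve` with
#'   columns `w_av, w_crit, x_e0, tau`, plus `w_star` and `jump_at`.
#' @export
critical_weight_curve <- function(model, w_av_grid, w_in_max = 40,
                                  tol = 1e-4, realization = NULL) {
  stopifnot(!is.unsorted(w_av_grid))
  rows <- lapply(w_av_grid, function(w_av) {
    eff <- effective_homogeneous(model, w_av, realization)
    eq <- equilibria(eff)
    st <- eq$x[eq$stable]
    # attained state: lowest stable root when bistable, else the unique one
    x_e0 <- if (!length(st)) NA_real_
            else if (length(st) > 1L) min(st) else st
    tau_net <- resilience_indicator(eff)$tau
    w_crit <- if (is.na(x_e0)) NA_real_ else
      node_wcrit_(model, eff$params, x_e0, w_in_max, tol)
    data.frame(w_av = w_av, w_crit = w_crit, x_e0 = x_e0, tau = tau_net)
  })
  curve <- do.call(rbind, rows)
  jump_at <- if (nrow(curve) > 1L) {
    d <- abs(diff(curve$w_crit))
    mean(curve$w_av[which.max(d) + c(0L, 1L)])
  } else NA_real_
  structure(list(curve = curve, jump_at = jump_at), class = "critical_curve")
}

node_tau_ <- function(model, p, x_e0, w_in) {
  one <- list(fn = function(x) model$f(x, p) + w_in * model$g(x, x_e0, p),
              x_max = model$x_max_fn(p))
  resilience_indicator(one)$tau
}

node_wcrit_ <- function(model, p, x_e0, w_in_max, tol) {
  if (node_tau_(model, p, x_e0, 0) > 0) return(0)
  if (node_tau_(model, p, x_e0, w_in_max) < 0) return(NA_real_)
  lo <- 0; hi <- w_in_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (node_tau_(model, p, x_e0, mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
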