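#' Reduced one-node dynamics from the sequential estimation
#'
#' Second step of the sequential scheme: neighbours of node `i` are
#' replaced by the mean-field healthy-equilibrium estimate \eqn{x_e^0},
#' and the coupling is averaged over potential neighbours proportionally
#' to their out-weight:
#' \deqn{\dot x_i = f(x_i, a) + w_i^{in} \frac{\sum_j w_j^{out}
#'   g(x_i, x_e^0, b_j)}{\sum_j w_j^{out}}.}
#' With homogeneous coupling parameters this is
#' \eqn{f(x) + w^{in} g(x, x_e^0)}.
#'
#' @param model a [dynamics_model()].
#' @param graph a [weighted_digraph()].
#' @param node node index (1-based).
#' @param x_e0 neighbour-state estimate (from [healthy_equilibrium()]).
#' @param realization values for uncertain parameters.
#' @return vectorised function of the node state.
#' @export
node_reduced_rhs <- function(model, graph, node, x_e0, realization = NULL) {
  stopifnot(is_weighted_digraph(graph), node >= 1, node <= graph$N)
  p <- resolve_params(model, realization)
  if ("w_ref" %in% names(p)) p$w_ref <- graph$w_av
  w_in <- graph$w_in[node]
  b_len <- if (length(model$b_names))
    vapply(p[model$b_names], length, 0L) else integer(0)
  if (w_in > 0 && graph$m == 0)
    stop("all out-weights are zero: neighbour averaging undefined")
  if (all(b_len <= 1L)) {
    function(x) model$f(x, p) + w_in * model$g(x, x_e0, p)
  } else {
    w_out <- graph$w_out
    if (sum(w_out) == 0) stop("all out-weights are zero")
    function(x) {
      acc <- 0
      for (j in seq_len(graph$N)) {
        pj <- p
        for (nm in model$b_names)
          if (length(pj[[nm]]) > 1L) pj[[nm]] <- pj[[nm]][j]
        acc <- acc + w_out[j] * model$g(x, x_e0, pj)
      }
      model$f(x, p) + w_in * acc / sum(w_out)
    }
  }
}

#' Node-level resilience indicator
#'
#' Runs both steps of the sequential estimation for one node at a fixed
#' realization: mean-field healthy equilibrium, reduced one-node dynamics,
#' then the local-minimum indicator \eqn{\tau^i} with the same search
#' policy as the network level.
#'
#' @inheritParams node_reduced_rhs
#' @return object of class `node_indicator`: `tau`, `x_min`, `resilient`,
#'   `x_e0`, `multiple`, `w_in`, `node`.
#' @export
node_indicator <- function(model, graph, node, realization = NULL) {
  he <- healthy_equilibrium(model, graph, realization)
  rhs <- node_reduced_rhs(model, graph, node, he$x_e0, realization)
  p <- resolve_params(model, realization)
  one <- list(fn = rhs, x_max = model$x_max_fn(p))
  ri <- resilience_indicator(one)
  structure(list(tau = ri$tau, x_min = ri$x_min, resilient = ri$resilient,
                 monotone = ri$monotone, x_e0 = he$x_e0,
                 multiple = he$multiple, w_in = graph$w_in[node],
                 node = node),
            class = "node_indicator")
}

## ---- batch evaluation over many shared-mode realizations -----------------
## All samples are processed as vectors: the state axis is handled by a
## common grid plus vectorised bisection, so cost is O(n_grid + n_iter)
## vectorised operations per batch instead of O(n_samples) scalar searches.

params_batch_ <- function(model, xi_mat) {
  p <- resolve_params(model)
  for (nm in colnames(xi_mat)) {
    if (!nm %in% names(p)) stop("unknown parameter in realization: ", nm)
    p[[nm]] <- xi_mat[, nm]
  }
  p
}

largest_root_batch_ <- function(FN, n, x_max, n_grid = 600L, iters = 50L) {
  k <- 0L  # extend until every sample's tail is negative
  while (any(FN(rep(x_max, n)) >= 0) && k < 60L) { x_max <- x_max * 1.5; k <- k + 1L }
  grid <- seq(0, x_max, length.out = n_grid)
  pos <- vapply(grid, function(xx) FN(rep(xx, n)) > 0, logical(n))
  if (n == 1L) pos <- matrix(pos, nrow = 1L)
  cross <- pos[, -n_grid, drop = FALSE] & !pos[, -1L, drop = FALSE]
  ok <- rowSums(cross) > 0
  if (!all(ok)) stop(sum(!ok), " sample(s) have no root on the scan domain")
  idx <- max.col(cross, ties.method = "last")
  lo <- grid[idx]; hi <- grid[idx + 1L]
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    sel <- FN(mid) > 0
    lo[sel] <- mid[sel]; hi[!sel] <- mid[!sel]
  }
  (lo + hi) / 2
}

first_localmin_batch_ <- function(FN, n, x_hi, n_grid = 600L, iters = 45L) {
  gmax <- max(x_hi)
  grid <- seq(0, gmax, length.out = n_grid)
  Y <- vapply(grid, function(xx) FN(rep(xx, n)), numeric(n))
  if (n == 1L) Y <- matrix(Y, nrow = 1L)
  inside <- outer(x_hi, grid, ">")
  mid <- 2:(n_grid - 1L)
  cand <- (Y[, mid, drop = FALSE] < Y[, mid - 1L, drop = FALSE]) &
          (Y[, mid, drop = FALSE] <= Y[, mid + 1L, drop = FALSE]) &
          inside[, mid, drop = FALSE]
  has <- rowSums(cand) > 0
  tau <- numeric(n); x_min <- numeric(n)
  if (any(!has)) {
    Ym <- Y; Ym[!inside] <- Inf
    Ym[, 1L] <- Inf  # open interval: x = 0 does not count
    j <- max.col(-Ym[!has, , drop = FALSE], ties.method = "first")
    tau[!has] <- Ym[cbind(which(!has), j)]
    x_min[!has] <- grid[j]
  }
  if (any(has)) {
    i2 <- max.col(cand[has, , drop = FALSE], ties.method = "first") + 1L
    a <- grid[i2 - 1L]; b <- grid[i2 + 1L]
    h <- gmax * 1e-7
    sub <- function(v) { full <- numeric(n); full[has] <- v; full }
    for (it in seq_len(iters)) {
      m2 <- (a + b) / 2
      d <- (FN(sub(m2 + h)) - FN(sub(m2 - h)))[has]
      dec <- d < 0
      a[dec] <- m2[dec]; b[!dec] <- m2[!dec]
    }
    xm <- (a + b) / 2
    tau[has] <- FN(sub(xm))[has]
    x_min[has] <- xm
  }
  list(tau = tau, x_min = x_min)
}

# network-level indicator tau and healthy equilibrium for a batch of
# shared-mode realizations (rows of xi_mat, named columns)
tau_eff_batch <- function(model, w_av, xi_mat, n_grid = 600L) {
  n <- nrow(xi_mat)
  p <- params_batch_(model, xi_mat)
  if ("w_ref" %in% names(p)) p$w_ref <- w_av
  FN <- function(xv) model$f(xv, p) + w_av * model$g(xv, xv, p)
  x_max <- model$x_max_fn(resolve_params(model))
  x_e0 <- largest_root_batch_(FN, n, x_max, n_grid)
  lm <- first_localmin_batch_(FN, n, x_e0, n_grid)
  list(tau = lm$tau, x_e0 = x_e0)
}

# node-level indicator for a batch of shared-mode realizations
tau_node_batch <- function(model, graph, node, xi_mat, n_grid = 600L) {
  n <- nrow(xi_mat)
  p <- params_batch_(model, xi_mat)
  if ("w_ref" %in% names(p)) p$w_ref <- graph$w_av
  x_max <- model$x_max_fn(resolve_params(model))
  FNe <- function(xv) model$f(xv, p) + graph$w_av * model$g(xv, xv, p)
  x_e0 <- largest_root_batch_(FNe, n, x_max, n_grid)
  w_in <- graph$w_in[node]
  FNn <- function(xv) model$f(xv, p) + w_in * model$g(xv, x_e0, p)
  x_h <- largest_root_batch_(FNn, n, x_max, n_grid)
  lm <- first_localmin_batch_(FNn, n, x_h, n_grid)
  list(tau = lm$tau, x_e0 = x_e0)
}

#' Fit a multivariate aPC surrogate to any indicator function
#'
#' Projects a scalar function of `l` independent uncertain inputs onto the
#' orthonormal aPC basis of total degree `r`.  Coefficients are computed
#' by tensorised Gauss quadrature (`r + 1` nodes per dimension; exact for
#' polynomial integrands of total degree `2r + 1`) for `l <= 3`, or by a
#' seeded least-squares fit on `2 Z` sampled design points for larger `l`.
#'
#' @param tau_fn function taking an `n x l` matrix of input values (named
#'   columns) and returning `n` indicator values.
#' @param inputs named list of [random_input()]s.
#' @param order total degree `r`.
#' @param method `"quadrature"`, `"least-squares"`, or `"auto"`.
#' @param n_valid held-out validation points.
#' @param seed seed for design/validation sampling.
#' @return object of class `apc_surrogate`: `basis`, `coef` (length `Z`),
#'   `method`, `resid` (RMS validation residual), `n_design`.
#' @export
fit_apc_surrogate <- function(tau_fn, inputs, order,
                              method = c("auto", "quadrature", "least-squares"),
                              n_valid = 32L, seed = 1L) {
  method <- match.arg(method)
  l <- length(inputs)
  stopifnot(l >= 1L, !is.null(names(inputs)))
  if (method == "auto") method <- if (l <= 3L) "quadrature" else "least-squares"
  mb <- multivariate_basis(inputs, order)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  if (method == "quadrature") {
    rules <- lapply(inputs, quadrature_rule, n_nodes = order + 1L)
    pts <- as.matrix(do.call(expand.grid, lapply(rules, `[[`, "nodes")))
    colnames(pts) <- names(inputs)
    Wg <- as.matrix(do.call(expand.grid, lapply(rules, `[[`, "weights")))
    W <- apply(Wg, 1, prod)
    tau <- tau_fn(pts)
    Phi <- evaluate_basis_matrix(mb, pts)
    coef <- drop(crossprod(Phi, W * tau))
  } else {
    set.seed(seed)
    n_design <- 2L * mb$Z
    pts <- vapply(inputs, ri_sample, numeric(n_design), n = n_design)
    colnames(pts) <- names(inputs)
    tau <- tau_fn(pts)
    Phi <- evaluate_basis_matrix(mb, pts)
    coef <- stats::lm.fit(Phi, tau)$coefficients
    coef[is.na(coef)] <- 0
  }
  set.seed(seed + 1L)
  val <- vapply(inputs, ri_sample, numeric(n_valid), n = n_valid)
  colnames(val) <- names(inputs)
  resid <- sqrt(mean((drop(evaluate_basis_matrix(mb, val) %*% coef) -
                        tau_fn(val))^2))
  structure(list(basis = mb, coef = unname(coef), method = method,
                 resid = resid, n_design = nrow(pts), order = as.integer(order),
                 inputs = inputs),
            class = "apc_surrogate")
}

#' @export
predict.apc_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = object$basis$l)
  drop(evaluate_basis_matrix(object$basis, newdata) %*% object$coef)
}

#' Multivariate aPC surrogate of a node's resilience indicator
#'
#' Wraps [fit_apc_surrogate()] around the sequential node indicator
#' \eqn{\tau^i(\xi_1, \dots, \xi_l)} (shared uncertainty mode: one draw of
#' each uncertain parameter applies to all nodes).
#'
#' @inheritParams node_reduced_rhs
#' @inheritParams fit_apc_surrogate
#' @param inputs named list of [random_input()]s; names must be model
#'   parameter names.  Defaults to the model's uncertain parameters.
#' @return an `apc_surrogate` with `node` and `w_in` recorded.
#' @export
fit_node_apc <- function(model, graph, node, inputs = NULL, order = 3L,
                         method = c("auto", "quadrature", "least-squares"),
                         n_valid = 32L, seed = 1L) {
  if (is.null(inputs)) {
    nm <- uncertain_names(model)
    inputs <- model$params[nm]
  }
  tau_fn <- function(xi_mat) tau_node_batch(model, graph, node, xi_mat)$tau
  out <- fit_apc_surrogate(tau_fn, inputs, order, method, n_valid, seed)
  out$node <- node
  out$w_in <- graph$w_in[node]
  out
}

#' Probability of node resilience from an aPC surrogate
#'
#' Seeded sampling of the inputs' product measure through the (cheap)
#' surrogate: \eqn{P(\tilde\tau^i > 0)} with a binomial standard error.
#'
#' @param surrogate an `apc_surrogate`.
#' @param inputs named list of [random_input()]s (defaults to those the
#'   surrogate was fitted with).
#' @param n_samples number of draws (default `1e5`).
#' @param seed RNG seed.
#' @return object of class `node_resilience_report`.
#' @export
node_resilience_probability <- function(surrogate, inputs = NULL,
                                        n_samples = 1e5, seed = 1L) {
  if (is.null(inputs)) inputs <- surrogate$inputs
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  pts <- vapply(inputs, ri_sample, numeric(n_samples), n = n_samples)
  p <- mean(predict(surrogate, pts) > 0)
  node_report(surrogate$node, surrogate$w_in, p,
              method = paste0("apc-", surrogate$method),
              order = surrogate$order, n = n_samples, seed = seed,
              se = sqrt(p * (1 - p) / n_samples))
}

#' Monte Carlo baseline for node resilience
#'
#' Direct sampling of parameter realizations with a full sequential
#' indicator evaluation per sample (no surrogate); the reference the aPC
#' estimates are judged against.
#'
#' @inheritParams fit_node_apc
#' @param n_samples number of realizations.
#' @param seed RNG seed.
#' @param chunk samples processed per vectorised batch.
#' @return object of class `node_resilience_report`.
#' @export
mc_node_probability <- function(model, graph, node, inputs = NULL,
                                n_samples = 2000L, seed = 1L, chunk = 2000L) {
  stopifnot(n_samples >= 1)
  if (is.null(inputs)) inputs <- model$params[uncertain_names(model)]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  pts <- vapply(inputs, ri_sample, numeric(n_samples), n = n_samples)
  if (n_samples == 1L) pts <- matrix(pts, 1L, dimnames = list(NULL, names(inputs)))
  n_pos <- 0L; n_fail <- 0L
  done <- 0L
  while (done < n_samples) {
    nb <- min(chunk, n_samples - done)
    xi <- pts[done + seq_len(nb), , drop = FALSE]
    tau <- tryCatch(tau_node_batch(model, graph, node, xi)$tau,
                    error = function(e) rep(NA_real_, nb))
    n_fail <- n_fail + sum(is.na(tau))
    n_pos <- n_pos + sum(tau > 0, na.rm = TRUE)
    done <- done + nb
  }
  if (n_fail > 0.01 * n_samples)
    stop(n_fail, " of ", n_samples, " indicator evaluations failed")
  p <- n_pos / (n_samples - n_fail)
  node_report(node, graph$w_in[node], p, method = "mc", order = NA_integer_,
              n = n_samples, seed = seed,
              se = sqrt(p * (1 - p) / (n_samples - n_fail)),
              n_failed = n_fail)
}

node_report <- function(node, w_in, p, method, order, n, seed, se,
                        n_failed = 0L) {
  stopifnot(p >= 0, p <= 1)
  structure(list(node = node, w_in = w_in, probability = p, method = method,
                 order = order, n = n, seed = seed, se = se,
                 n_failed = n_failed),
            class = "node_resilience_report")
}

#' @export
print.node_resilience_report <- function(x, ...) {
  cat(sprintf("<node_resilience_report> node %s: P = %.4f (%s, n = %g, se %.2g)\n",
              as.character(x$node), x$probability, x$method, x$n, x$se))
  invisible(x)
}

#' Node resilience under observation noise
#'
#' With additive noise \eqn{\gamma} on the reduced node dynamics whose
#' deterministic indicator is \eqn{\tau_2}, the node is resilient when
#' \eqn{\tau_2 + \gamma > 0}; the probability is \eqn{P(\gamma > -\tau_2)}
#' under the noise law (closed form per family).  `strict_literal = TRUE`
#' instead integrates the noise density from \eqn{\tau_2} upward, an
#' alternative printed convention kept for comparison.
#'
#' @param tau2 deterministic node indicator.
#' @param noise a [random_input()].
#' @param strict_literal use the lower limit `tau2` instead of `-tau2`.
#' @return a `resilience_probability` (method `"closed-form"`).
#' @export
obs_noise_node_probability <- function(tau2, noise, strict_literal = FALSE) {
  thr <- if (strict_literal) tau2 else -tau2
  s <- noise$spec
  p <- switch(noise$kind,
    gaussian = stats::pnorm(thr, s$mean, s$sd, lower.tail = FALSE),
    uniform  = stats::punif(thr, s$lower, s$upper, lower.tail = FALSE),
    beta     = stats::pbeta((thr - s$lower) / (s$upper - s$lower),
                            s$shape1, s$shape2, lower.tail = FALSE),
    gamma    = stats::pgamma(thr, shape = s$shape, rate = s$rate,
                             lower.tail = FALSE),
    discrete = sum(s$probs[s$values > thr]),
    samples  = mean(s$x > thr),
    moments  = {
      n_nodes <- max(1L, (length(s$mu) - 1L) %/% 2L)
      q <- quadrature_rule(noise, n_nodes)
      sum(q$weights[q$nodes > thr])
    })
  resilience_probability(p, "closed-form")
}
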