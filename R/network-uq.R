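#' Central-limit statistics of the uncertain mean-field terms
#'
#' With independent per-node parameter draws (`"iid"` mode), the node
#' averages \eqn{\frac1N\sum_i f(x, a_i)} and the coupling double sum are
#' asymptotically Gaussian.  This computes their pointwise mean and
#' standard-deviation functions \eqn{\mu_f(x), \delta_f(x), \mu_g(x),
#' \delta_g(x)} by tensorised Gauss quadrature over the uncertain
#' parameters.
#'
#' @param model a [dynamics_model()] (its `"iid"` mode is the CLT regime).
#' @param x_grid grid on which the statistics are tabulated (they are also
#'   returned as exact callables, so the grid is for inspection only).
#' @param n_quad quadrature nodes per uncertain dimension.
#' @return object of class `clt_statistics` with vectorised functions
#'   `mu_f`, `delta_f`, `mu_g`, `delta_g`, the tabulation `table`, and the
#'   model.
#' @export
clt_statistics <- function(model, x_grid = NULL, n_quad = 8L) {
  unc <- uncertain_names(model)
  unc_a <- intersect(unc, model$a_names)
  unc_b <- intersect(unc, model$b_names)
  p0 <- resolve_params(model)
  make_stats <- function(fun, unc_names) {
    if (!length(unc_names)) {
      mu <- function(x) fun(x, p0)
      de <- function(x) rep(0, length(x))
      return(list(mu = mu, delta = de))
    }
    rules <- lapply(unc_names, function(nm)
      quadrature_rule(model$params[[nm]], n_quad))
    names(rules) <- unc_names
    combos <- do.call(expand.grid, lapply(rules, function(r) seq_along(r$nodes)))
    W <- apply(vapply(seq_along(unc_names), function(j)
      rules[[j]]$weights[combos[, j]], numeric(nrow(combos))), 1, prod)
    vals_at <- function(x) {
      v1 <- 0; v2 <- 0
      for (q in seq_len(nrow(combos))) {
        pq <- p0
        for (j in seq_along(unc_names))
          pq[[unc_names[j]]] <- rules[[j]]$nodes[combos[q, j]]
        fv <- fun(x, pq)
        v1 <- v1 + W[q] * fv
        v2 <- v2 + W[q] * fv^2
      }
      list(mu = v1, var = pmax(v2 - v1^2, 0))
    }
    list(mu = function(x) vals_at(x)$mu,
         delta = function(x) sqrt(vals_at(x)$var))
  }
  sf <- make_stats(function(x, p) model$f(x, p), unc_a)
  sg <- make_stats(function(x, p) model$g(x, x, p), unc_b)
  tab <- if (!is.null(x_grid))
    data.frame(x = x_grid, mu_f = sf$mu(x_grid), delta_f = sf$delta(x_grid),
               mu_g = sg$mu(x_grid), delta_g = sg$delta(x_grid))
  else NULL
  structure(list(mu_f = sf$mu, delta_f = sf$delta,
                 mu_g = sg$mu, delta_g = sg$delta,
                 table = tab, model = model, n_quad = n_quad),
            class = "clt_statistics")
}

#' Gaussian realization of the uncertain effective dynamics
#'
#' One draw of the mean-field right-hand side under the CLT reduction:
#' \deqn{\Xi_\zeta(x) = \mu_f(x) + \frac{m}{N}\mu_g(x) +
#'   \sqrt{\tfrac1N \delta_f(x)^2 + \tfrac{m}{N^2}\delta_g(x)^2}\; \zeta,}
#' with \eqn{\zeta} standard normal.  At \eqn{\zeta = 0} this is the mean
#' curve; the spread shrinks like \eqn{1/\sqrt N}.
#'
#' @param stats a [clt_statistics()].
#' @param graph the [weighted_digraph()] supplying `m` and `N`.
#' @param zeta standard-normal driver value.
#' @return an `effective_dynamics` object (works with [equilibria()],
#'   [resilience_indicator()], ...).
#' @export
xi_realization <- function(stats, graph, zeta) {
  stopifnot(inherits(stats, "clt_statistics"), is_weighted_digraph(graph))
  if (graph$N < 30)
    warning("CLT reduction with N = ", graph$N, " (< 30) is unreliable")
  m <- graph$m; N <- graph$N
  fn <- function(x)
    stats$mu_f(x) + (m / N) * stats$mu_g(x) +
      sqrt(stats$delta_f(x)^2 / N + m * stats$delta_g(x)^2 / N^2) * zeta
  p0 <- resolve_params(stats$model)
  structure(list(fn = fn, x_max = stats$model$x_max_fn(p0),
                 model = stats$model, w_av = graph$w_av, zeta = zeta),
            class = "effective_dynamics")
}

#' Hermite polynomial-chaos surrogate of the network resilience indicator
#'
#' Evaluates \eqn{\tau(\zeta)} (the mean-field local-minimum indicator of
#' [xi_realization()]) at Gauss--Hermite nodes and projects onto the
#' normalised probabilists' Hermite basis by discrete projection.
#'
#' @inheritParams xi_realization
#' @param order truncation degree `r`.
#' @param n_quad number of Gauss--Hermite nodes (default `2*order + 2`).
#' @param zeta_valid held-out driver values for the validation residual.
#' @return object of class `pce_surrogate`: `coef` (length `order + 1`),
#'   `basis`, `resid` (max abs validation error), `tau_nodes`.
#' @export
fit_tau_pce <- function(stats, graph, order = 3L, n_quad = 2L * order + 2L,
                        zeta_valid = seq(-2.5, 2.5, length.out = 9L)) {
  stopifnot(order >= 1L, n_quad >= order + 1L)
  gauss <- random_input("gaussian")
  rule <- quadrature_rule(gauss, n_quad)
  basis <- apc_basis(gauss, order)
  tau_at <- function(z) {
    eff <- xi_realization(stats, graph, z)
    ri <- tryCatch(resilience_indicator(eff), error = function(e)
      stop("indicator undefined at zeta = ", signif(z, 4), ": ",
           conditionMessage(e)))
    ri$tau
  }
  tau_nodes <- vapply(rule$nodes, tau_at, 0)
  Phi <- vapply(0:order, function(d) eval_basis_poly(basis, rule$nodes, d),
                numeric(n_quad))
  coef <- drop(crossprod(Phi, rule$weights * tau_nodes))
  tau_val <- vapply(zeta_valid, tau_at, 0)
  Phi_val <- vapply(0:order, function(d) eval_basis_poly(basis, zeta_valid, d),
                    numeric(length(zeta_valid)))
  resid <- max(abs(drop(Phi_val %*% coef) - tau_val))
  structure(list(order = as.integer(order), coef = coef, basis = basis,
                 resid = resid, tau_nodes = tau_nodes, nodes = rule$nodes),
            class = "pce_surrogate")
}

#' @export
predict.pce_surrogate <- function(object, zeta, ...) {
  Phi <- vapply(0:object$order, function(d)
    eval_basis_poly(object$basis, zeta, d), numeric(length(zeta)))
  drop(Phi %*% object$coef)
}

#' Probability of network-level resilience
#'
#' \eqn{P(\tilde\tau_r(\zeta) > 0)} under the standard-normal driver.  The
#' analytic method finds all real roots of the degree-r surrogate
#' polynomial and sums the Gaussian measure of the intervals where it is
#' positive (exact for the surrogate); the Monte Carlo method samples
#' \eqn{\zeta}.
#'
#' @param surrogate a [fit_tau_pce()] surrogate.
#' @param method `"analytic"` or `"mc"`.
#' @param n_samples,seed Monte Carlo settings.
#' @return object of class `resilience_probability`: `value`, `method`,
#'   `se` (standard error, `NA` for analytic).
#' @export
network_resilience_probability <- function(surrogate,
                                           method = c("analytic", "mc"),
                                           n_samples = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (method == "mc") {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    z <- stats::rnorm(n_samples)
    p <- mean(predict(surrogate, z) > 0)
    return(resilience_probability(p, "mc",
                                  se = sqrt(p * (1 - p) / n_samples)))
  }
  # assemble monomial coefficients of the surrogate
  cf <- numeric(surrogate$order + 1L)
  for (k in 0:surrogate$order) {
    ck <- surrogate$basis$coef[[k + 1L]]
    cf[seq_along(ck)] <- cf[seq_along(ck)] + surrogate$coef[k + 1L] * ck
  }
  p <- positive_normal_measure(cf)
  resilience_probability(p, "pce-analytic")
}

# Gaussian measure of {x : poly(x) > 0}, poly in ascending coefficients
positive_normal_measure <- function(cf) {
  cf <- poly_trim(cf, tol = max(abs(cf)) * 1e-14)
  if (length(cf) == 1L) return(as.numeric(cf > 0))
  rt <- polyroot(cf)
  re <- sort(Re(rt[abs(Im(rt)) < 1e-8 * (1 + abs(Re(rt)))]))
  pts <- unique(re)
  bounds <- c(-Inf, pts, Inf)
  test <- c(if (length(pts)) pts[1] - 1 else 0,
            if (length(pts) > 1) (pts[-1] + pts[-length(pts)]) / 2,
            if (length(pts)) pts[length(pts)] + 1 else NULL)
  if (!length(pts)) test <- 0
  total <- 0
  for (i in seq_along(test)) {
    if (polyval(cf, test[i]) > 0)
      total <- total + stats::pnorm(bounds[i + 1L]) - stats::pnorm(bounds[i])
  }
  total
}

resilience_probability <- function(value, method, se = NA_real_) {
  stopifnot(value >= -1e-12, value <= 1 + 1e-12)
  structure(list(value = min(max(value, 0), 1), method = method, se = se),
            class = "resilience_probability")
}

#' @export
print.resilience_probability <- function(x, ...) {
  cat(sprintf("<resilience_probability> %.6g (%s%s)\n", x$value, x$method,
              if (is.finite(x$se)) sprintf(", se %.2g", x$se) else ""))
  invisible(x)
}

#' Network resilience under observation noise (closed form)
#'
#' With additive observation noise \eqn{\gamma_i} on every node, the
#' mean-field indicator becomes \eqn{\tau_1 + \frac1N\sum_i\gamma_i}; the
#' CLT makes the noise average Gaussian, giving
#' \deqn{P = \Phi\!\left(\frac{(\tau_1 + \mu_\gamma)\sqrt N}
#'   {\delta_\gamma}\right).}
#'
#' @param tau1 local-minimum indicator of the deterministic part.
#' @param noise a [random_input()] describing one node's noise.
#' @param N number of nodes (>= 1).
#' @return a `resilience_probability` (method `"closed-form"`).
#' @export
obs_noise_network_probability <- function(tau1, noise, N) {
  stopifnot(N >= 1)
  mu_g <- ri_mean(noise); de_g <- ri_sd(noise)
  p <- if (de_g == 0) as.numeric(tau1 + mu_g > 0)
       else stats::pnorm((tau1 + mu_g) * sqrt(N) / de_g)
  resilience_probability(p, "closed-form")
}

#' Kolmogorov--Smirnov check of the CLT reduction
#'
#' Draws `n_rep` replicates of the node-averaged self-dynamics
#' \eqn{\frac1N\sum_i f(x, a_i)} with iid per-node parameter draws,
#' standardises by the quadrature-exact \eqn{\mu_f(x)} and
#' \eqn{\delta_f(x)/\sqrt N}, and returns the KS distance from the
#' standard normal.
#'
#' @param model a [dynamics_model()] with at least one uncertain parameter
#'   in its self-dynamics.
#' @param x state value at which `f` is evaluated.
#' @param N nodes per replicate.
#' @param n_rep number of replicates.
#' @param seed RNG seed.
#' @return KS statistic (numeric scalar).
#' @export
clt_ks_distance <- function(model, x, N = 1000L, n_rep = 1e4, seed = 1L) {
  unc_a <- intersect(uncertain_names(model), model$a_names)
  if (!length(unc_a)) stop("model has no uncertain self-dynamics parameter")
  st <- clt_statistics(model)
  mu <- st$mu_f(x); de <- st$delta_f(x)
  if (de <= 0) stop("delta_f is zero at x = ", x)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  p0 <- resolve_params(model)
  means <- numeric(n_rep)
  block <- max(1L, floor(2e6 / N))
  done <- 0L
  while (done < n_rep) {
    nb <- min(block, n_rep - done)
    pq <- p0
    for (nm in unc_a)
      pq[[nm]] <- matrix(ri_sample(model$params[[nm]], N * nb), N, nb)
    fv <- model$f(x, pq)
    means[done + seq_len(nb)] <- colMeans(fv)
    done <- done + nb
  }
  z <- sort((means - mu) / (de / sqrt(N)))
  u <- stats::pnorm(z)
  n <- length(z)
  max(pmax(abs(seq_len(n) / n - u), abs(u - (seq_len(n) - 1) / n)))
}
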