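#' Uncertain parameters of arbitrary distribution
#'
#' A `random_input` describes one independent uncertain scalar parameter.  It
#' can be specified three ways, mirroring the kinds of statistical
#' information available in practice:
#'
#' * a **named distribution** (`uniform`, `gaussian`, `beta`, `gamma`,
#'   `discrete`) with its parameters,
#' * a finite set of **empirical samples** (raw data, used directly through
#'   plug-in sample moments -- no smoothing), or
#' * a finite **raw moment sequence** \eqn{\mu_0, \mu_1, \dots} (with
#'   \eqn{\mu_0 = 1}).
#'
#' All downstream machinery (orthonormal polynomial bases, Gauss quadrature,
#' sampling) is driven by raw moments \eqn{\mu_k = E[\xi^k]}, which is what
#' makes arbitrary polynomial chaos applicable to any of the three kinds.
#'
#' @param kind one of `"uniform"`, `"gaussian"`, `"beta"`, `"gamma"`,
#'   `"discrete"`, `"samples"`, `"moments"`.
#' @param ... distribution parameters: `lower`/`upper` (uniform),
#'   `mean`/`sd` (gaussian), `shape1`/`shape2` and optional `lower`/`upper`
#'   support (beta), `shape`/`rate` (gamma), `values`/`probs` (discrete),
#'   `x` (samples), `mu` (moments, starting at \eqn{\mu_0}).
#' @param label optional identifier used in reports.
#' @return an object of class `random_input`.
#' @examples
#' xi <- random_input("uniform", lower = -1, upper = 1)
#' raw_moments(xi, 4)$values   # 1, 0, 1/3, 0, 1/5
#' @export
random_input <- function(kind, ..., label = NULL) {
  kind <- match.arg(kind, c("uniform", "gaussian", "beta", "gamma",
                            "discrete", "samples", "moments"))
  args <- list(...)
  spec <- switch(kind,
    uniform = {
      lo <- args$lower; hi <- args$upper
      stopifnot(is.numeric(lo), is.numeric(hi))
      if (!(hi > lo)) stop("uniform input needs upper > lower")
      list(lower = lo, upper = hi)
    },
    gaussian = {
      m <- if (is.null(args$mean)) 0 else args$mean
      s <- if (is.null(args$sd)) 1 else args$sd
      if (!(s > 0)) stop("gaussian input needs sd > 0")
      list(mean = m, sd = s)
    },
    beta = {
      a <- args$shape1; b <- args$shape2
      if (!(a > 0 && b > 0)) stop("beta input needs positive shapes")
      lo <- if (is.null(args$lower)) 0 else args$lower
      hi <- if (is.null(args$upper)) 1 else args$upper
      if (!(hi > lo)) stop("beta support needs upper > lower")
      list(shape1 = a, shape2 = b, lower = lo, upper = hi)
    },
    gamma = {
      k <- args$shape; r <- if (is.null(args$rate)) 1 else args$rate
      if (!(k > 0 && r > 0)) stop("gamma input needs positive shape and rate")
      list(shape = k, rate = r)
    },
    discrete = {
      v <- args$values; p <- args$probs
      if (is.null(p)) p <- rep(1 / length(v), length(v))
      stopifnot(length(v) == length(p))
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
        stop("discrete input needs nonnegative probs summing to 1")
      list(values = as.numeric(v), probs = as.numeric(p))
    },
    samples = {
      x <- as.numeric(args$x)
      if (length(x) < 2L) stop("empirical input needs at least 2 samples")
      if (stats::var(x) <= 0) stop("empirical input needs positive variance")
      list(x = x)
    },
    moments = {
      mu <- as.numeric(args$mu)
      if (abs(mu[1] - 1) > 1e-12) stop("moment sequence must start with mu0 = 1")
      check_moment_sequence(mu)
      list(mu = mu)
    })
  structure(list(kind = kind, spec = spec,
                 label = if (is.null(label)) kind else label),
            class = "random_input")
}

# Hankel positive-semidefiniteness of a raw moment sequence
check_moment_sequence <- function(mu) {
  n <- (length(mu) + 1L) %/% 2L
  H <- outer(seq_len(n), seq_len(n), function(i, j) mu[i + j - 1L])
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1))
    stop("moment sequence is not positive semidefinite (no generating measure)")
  k2 <- mu[3] - mu[2]^2
  if (length(mu) >= 3L && k2 < -1e-12)
    stop("moment sequence implies negative variance")
  invisible(TRUE)
}

#' @export
print.random_input <- function(x, ...) {
  cat("<random_input>", x$label, "kind:", x$kind, "\n")
  invisible(x)
}

is_random_input <- function(x) inherits(x, "random_input")

#' Raw moments of an uncertain input
#'
#' Computes \eqn{\mu_k = E[\xi^k]} for `k = 0..max_order`.  Named
#' distributions use closed forms, empirical samples use power-sum averages,
#' and moment-sequence inputs are validated and passed through.
#'
#' @param input a [random_input()].
#' @param max_order highest moment order required (non-negative integer).
#' @return an object of class `moment_table` with fields `max_order` and
#'   `values` (numeric vector of length `max_order + 1`, `values[1]` =
#'   \eqn{\mu_0} = 1).
#' @export
raw_moments <- function(input, max_order) {
  stopifnot(is_random_input(input), max_order >= 0)
  max_order <- as.integer(max_order)
  k <- 0:max_order
  s <- input$spec
  mu <- switch(input$kind,
    uniform = {
      a <- s$lower; b <- s$upper
      (b^(k + 1) - a^(k + 1)) / ((k + 1) * (b - a))
    },
    gaussian = {
      m <- numeric(max_order + 1L); m[1] <- 1
      if (max_order >= 1) m[2] <- s$mean
      if (max_order >= 2)
        for (j in 2:max_order)
          m[j + 1] <- s$mean * m[j] + (j - 1) * s$sd^2 * m[j - 1]
      m
    },
    beta = {
      # moments on [0,1] then affine map to [lower, upper]
      m01 <- numeric(max_order + 1L); m01[1] <- 1
      if (max_order >= 1)
        for (j in 1:max_order)
          m01[j + 1] <- m01[j] * (s$shape1 + j - 1) / (s$shape1 + s$shape2 + j - 1)
      affine_moments(m01, s$lower, s$upper - s$lower)
    },
    gamma = {
      m <- numeric(max_order + 1L); m[1] <- 1
      if (max_order >= 1)
        for (j in 1:max_order) m[j + 1] <- m[j] * (s$shape + j - 1) / s$rate
      m
    },
    discrete = vapply(k, function(kk) sum(s$probs * s$values^kk), 0),
    samples  = vapply(k, function(kk) mean(s$x^kk), 0),
    moments  = {
      if (max_order + 1L > length(s$mu))
        stop("requested moment order ", max_order,
             " exceeds the supplied sequence (max ", length(s$mu) - 1L, ")")
      s$mu[k + 1]
    })
  structure(list(max_order = max_order, values = mu), class = "moment_table")
}

# raw moments of a + b*X from raw moments of X
affine_moments <- function(mu, a, b) {
  n <- length(mu) - 1L
  vapply(0:n, function(k) {
    j <- 0:k
    sum(choose(k, j) * a^(k - j) * b^j * mu[j + 1])
  }, 0)
}

#' @export
print.moment_table <- function(x, ...) {
  cat("<moment_table> orders 0..", x$max_order, "\n", sep = "")
  print(x$values)
  invisible(x)
}

# moments of the standardised variable (x - mean)/sd, computed per kind to
# avoid the catastrophic cancellation of transforming raw moments when the
# support sits far from the origin
standardized_moments <- function(input, max_order) {
  m1 <- ri_mean(input); s <- ri_sd(input)
  if (s <= 0) stop("degenerate (zero-variance) input")
  sp <- input$spec
  k <- 0:max_order
  switch(input$kind,
    uniform = raw_moments(
      random_input("uniform", lower = (sp$lower - m1) / s,
                   upper = (sp$upper - m1) / s), max_order)$values,
    gaussian = raw_moments(random_input("gaussian"), max_order)$values,
    beta = {
      m01 <- raw_moments(random_input("beta", shape1 = sp$shape1,
                                      shape2 = sp$shape2), max_order)$values
      affine_moments(m01, (sp$lower - m1) / s, (sp$upper - sp$lower) / s)
    },
    gamma = {
      # rate-1 moments are O((shape + k)!); standardise (Y - shape)/sqrt(shape)
      m <- raw_moments(random_input("gamma", shape = sp$shape, rate = 1),
                       max_order)$values
      affine_moments(m, -sqrt(sp$shape), 1 / sqrt(sp$shape))
    },
    discrete = {
      z <- (sp$values - m1) / s
      vapply(k, function(kk) sum(sp$probs * z^kk), 0)
    },
    samples = {
      z <- (sp$x - m1) / s
      vapply(k, function(kk) mean(z^kk), 0)
    },
    moments = affine_moments(raw_moments(input, max_order)$values,
                             -m1 / s, 1 / s))
}

ri_mean <- function(input) raw_moments(input, 1L)$values[2]

ri_sd <- function(input) {
  m <- raw_moments(input, 2L)$values
  sqrt(max(m[3] - m[2]^2, 0))
}

#' Draw random samples from an uncertain input
#'
#' Moment-sequence inputs have no unique generating law; they are sampled
#' from the n-point Gauss discrete measure that matches their moments (n as
#' large as the supplied sequence allows), which is the canonical
#' moment-matching surrogate measure.
#'
#' @param input a [random_input()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
ri_sample <- function(input, n) {
  s <- input$spec
  switch(input$kind,
    uniform  = stats::runif(n, s$lower, s$upper),
    gaussian = stats::rnorm(n, s$mean, s$sd),
    beta     = s$lower + (s$upper - s$lower) * stats::rbeta(n, s$shape1, s$shape2),
    gamma    = stats::rgamma(n, shape = s$shape, rate = s$rate),
    discrete = sample(s$values, n, replace = TRUE, prob = s$probs),
    samples  = sample(s$x, n, replace = TRUE),
    moments  = {
      n_nodes <- max(1L, (length(s$mu) - 1L) %/% 2L)
      q <- quadrature_rule(input, n_nodes)
      sample(q$nodes, n, replace = TRUE, prob = q$weights)
    })
}
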