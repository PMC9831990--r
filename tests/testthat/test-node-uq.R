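# Sequential node-level estimation, multivariate aPC surrogates, MC baseline.

test_that("reduced node dynamics matches hand evaluation and decoupled limit", {
  mod <- fix_model()
  g2 <- weighted_digraph(matrix(c(0, 5, 5, 0), 2, 2))
  rhs <- node_reduced_rhs(mod, g2, 1, x_e0 = 5)
  # f(2) + w_in * g(2, 5) = 1.3 + 7 * 10/7.3  (w_in = 5 gives 1.3 + 5*10/7.3)
  expect_equal(rhs(2), 1.3 + 5 * 10 / 7.3, tolerance = 1e-12)
  g7 <- weighted_digraph(matrix(c(0, 7, 7, 0), 2, 2))
  expect_equal(node_reduced_rhs(mod, g7, 1, 5)(2), 1.3 + 70 / 7.3,
               tolerance = 1e-12)

  # w_in = 0: exactly the self-dynamics
  M <- matrix(0, 3, 3); M[1, 2] <- 2; M[2, 3] <- 1
  g <- weighted_digraph(M)   # node 1 has no in-edges
  rhs0 <- node_reduced_rhs(mod, g, 1, x_e0 = 5)
  xg <- seq(0, 8, length.out = 33)
  p <- resolve_params(mod)
  expect_equal(rhs0(xg), mod$f(xg, p))

  # per-node coupling parameters are averaged with out-weights
  modu <- fix_case_a_model()
  E_nodes <- c(0.8, 0.9, 1.0)
  rhs_h <- node_reduced_rhs(modu, g, 3, x_e0 = 4,
                            realization = list(C = 1, E = E_nodes))
  manual <- function(x) {
    gv <- vapply(1:3, function(j) {
      pj <- p; pj$E <- E_nodes[j]
      modu$g(x, 4, pj)
    }, numeric(length(x)))
    mod$f(x, p) + g$w_in[3] * drop(gv %*% g$w_out) / sum(g$w_out)
  }
  expect_equal(rhs_h(xg), manual(xg), tolerance = 1e-12)
})

test_that("node indicator reproduces the decoupled dip and threshold logic", {
  mod <- fix_model()
  M <- matrix(0, 3, 3); M[1, 2] <- 2; M[2, 3] <- 1
  g <- weighted_digraph(M)
  ni <- node_indicator(mod, g, 1)          # no in-edges: bare self-dynamics
  orc <- optimize(function(x) 0.1 - x^3 / 5 + 1.2 * x^2 - x, c(0, 1),
                  tol = 1e-10)
  expect_equal(ni$tau, orc$objective, tolerance = 1e-6)
  expect_false(ni$resilient)
  expect_equal(ni$w_in, 0)

  # above threshold with comfortable in-weight the node is resilient
  gg <- fix_graph(N = 30, w_av = 8)
  nd <- which.max(gg$w_in)
  expect_gt(node_indicator(mod, gg, nd)$tau, 0)
})

test_that("batch indicator evaluation equals the scalar path", {
  mod <- fix_case_a_model()
  g <- fix_vulnerable_graph()
  set.seed(31)
  xi <- cbind(C = runif(6, 0.9, 1.1), E = runif(6, 0.81, 0.99))
  tb <- netres:::tau_node_batch(mod, g, 1, xi)
  for (i in seq_len(6)) {
    ni <- node_indicator(mod, g, 1, realization = list(C = xi[i, "C"],
                                                       E = xi[i, "E"]))
    expect_equal(tb$tau[i], ni$tau, tolerance = 1e-7)
    expect_equal(tb$x_e0[i], ni$x_e0, tolerance = 1e-9)
  }
})

test_that("aPC surrogates reproduce polynomial indicators exactly", {
  u <- function(lab) random_input("uniform", lower = -1, upper = 1, label = lab)
  inputs <- list(x1 = u("x1"), x2 = u("x2"))
  sur <- fit_apc_surrogate(function(m) 2 + 3 * m[, "x1"] * m[, "x2"],
                           inputs, order = 2)
  expect_lt(sur$resid, 1e-10)
  set.seed(8)
  pts <- cbind(x1 = runif(100, -1, 1), x2 = runif(100, -1, 1))
  expect_equal(predict(sur, pts), 2 + 3 * pts[, 1] * pts[, 2],
               tolerance = 1e-10)

  # projection identities: tau = x1^2 has constant coefficient E[x1^2] = 1/3
  sq <- fit_apc_surrogate(function(m) m[, "x1"]^2, inputs["x1"], order = 2)
  expect_equal(sq$coef[1], 1/3, tolerance = 1e-12)
  # truncating at r = 1 leaves only the constant (odd moments vanish)
  sq1 <- fit_apc_surrogate(function(m) m[, "x1"]^2, inputs["x1"], order = 1)
  expect_equal(sq1$coef, c(1/3, 0), tolerance = 1e-12)
  expect_equal(predict(sq1, matrix(c(-0.5, 0.9), ncol = 1)), c(1/3, 1/3),
               tolerance = 1e-12)
})

test_that("polynomial exactness holds across input kinds", {
  set.seed(12)
  kinds <- list(
    uniform = random_input("uniform", lower = -1, upper = 1),
    gaussian = random_input("gaussian"),
    beta = random_input("beta", shape1 = 2, shape2 = 5),
    empirical = random_input("samples", x = rgamma(1e5, 4, 2)))
  for (nm in names(kinds)) {
    inputs <- list(a = kinds[[nm]], b = random_input("uniform", lower = 0, upper = 1))
    tau_fn <- function(m) 1 - 2 * m[, "a"] + 0.5 * m[, "a"] * m[, "b"]^2
    sur <- fit_apc_surrogate(tau_fn, inputs, order = 3)
    pts <- cbind(a = ri_sample(inputs$a, 100), b = runif(100))
    expect_equal(predict(sur, pts), tau_fn(pts), tolerance = 1e-8)
  }
})

test_that("least-squares fitting agrees with quadrature on smooth fixtures", {
  u <- function(lab) random_input("uniform", lower = -1, upper = 1, label = lab)
  inputs <- list(x1 = u("x1"), x2 = u("x2"), x3 = u("x3"), x4 = u("x4"))
  tau_fn <- function(m) m[, "x1"] + m[, "x2"] * m[, "x3"] - 0.3 * m[, "x4"]
  ls <- fit_apc_surrogate(tau_fn, inputs, order = 2, method = "least-squares",
                          seed = 4)
  expect_identical(ls$method, "least-squares")
  expect_lt(ls$resid, 1e-9)                 # polynomial recovered from 2Z pts
  expect_equal(ls$n_design, 2L * choose(6, 2))
})

test_that("surrogate probabilities match uniform closed forms", {
  u <- list(x1 = random_input("uniform", lower = -1, upper = 1, label = "x1"))
  fit1 <- function(fn) fit_apc_surrogate(fn, u, order = 1)
  p_const <- node_resilience_probability(fit1(function(m) rep(1, nrow(m))),
                                         n_samples = 1e4, seed = 1)
  expect_equal(p_const$probability, 1)
  p_sym <- node_resilience_probability(fit1(function(m) m[, "x1"]),
                                       n_samples = 1e5, seed = 1)
  expect_lt(abs(p_sym$probability - 0.5), 3 * p_sym$se)
  p_shift <- node_resilience_probability(fit1(function(m) 0.5 + m[, "x1"]),
                                         n_samples = 1e5, seed = 1)
  expect_lt(abs(p_shift$probability - 0.75), 3 * p_shift$se)
})

test_that("Monte Carlo baseline is deterministic per seed and sane", {
  mod <- fix_case_a_model()
  g <- fix_vulnerable_graph()
  r1 <- mc_node_probability(mod, g, 1, n_samples = 400, seed = 11)
  r2 <- mc_node_probability(mod, g, 1, n_samples = 400, seed = 11)
  expect_identical(r1$probability, r2$probability)
  expect_gte(r1$probability, 0); expect_lte(r1$probability, 1)
  expect_equal(r1$method, "mc")

  # point-mass uncertainty: effectively deterministic, tau > 0 => P = 1
  mod_det <- mutualistic_model(
    C = random_input("discrete", values = 1, probs = 1, label = "C"))
  gg <- fix_graph(N = 30, w_av = 8)
  nd <- which.max(gg$w_in)
  r <- mc_node_probability(mod_det, gg, nd, n_samples = 50, seed = 2)
  expect_equal(r$probability, 1)
})

test_that("aPC and Monte Carlo agree on the marginal-node fixture", {
  mod <- fix_case_a_model()
  g <- fix_vulnerable_graph()
  sur <- fit_node_apc(mod, g, 1, order = 3)
  pa <- node_resilience_probability(sur, n_samples = 1e4, seed = 5)
  pm <- mc_node_probability(mod, g, 1, n_samples = 1e4, seed = 6)
  se <- sqrt(pa$se^2 + pm$se^2)
  expect_lt(abs(pa$probability - pm$probability), 3 * se + 0.01)
  expect_gt(pa$probability, 0.05); expect_lt(pa$probability, 0.95)
})

test_that("node observation-noise probabilities use the consistent condition", {
  gaussn <- random_input("gaussian")
  expect_equal(obs_noise_node_probability(0, gaussn)$value, 0.5)
  unif <- random_input("uniform", lower = -1, upper = 1)
  expect_equal(obs_noise_node_probability(0.5, unif)$value, 0.75)
  expect_equal(obs_noise_node_probability(0.5, unif, strict_literal = TRUE)$value,
               0.25)
  atom <- random_input("discrete", values = 0, probs = 1)   # delta -> 0
  expect_equal(obs_noise_node_probability(0.3, atom)$value, 1)
  # empirical and beta noise against direct CDF oracles
  set.seed(20)
  xs <- rnorm(5e4, 0.1, 0.3)
  emp <- random_input("samples", x = xs)
  expect_equal(obs_noise_node_probability(0.2, emp)$value, mean(xs > -0.2))
  bet <- random_input("beta", shape1 = 2, shape2 = 3)
  expect_equal(obs_noise_node_probability(-0.4, bet)$value,
               1 - pbeta(0.4, 2, 3), tolerance = 1e-12)
})
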