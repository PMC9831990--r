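# Moment machinery and aPC basis construction.

test_that("raw moments match closed forms and degenerate cases", {
  u <- random_input("uniform", lower = -1, upper = 1)
  expect_equal(raw_moments(u, 4)$values, c(1, 0, 1/3, 0, 1/5))

  pm <- random_input("discrete", values = 2.5, probs = 1)
  expect_equal(raw_moments(pm, 3)$values, 2.5^(0:3))

  # Gaussian moment recursion mu_k = (k-1) mu_{k-2}
  gn <- random_input("gaussian")
  mu <- c(1, 0)
  for (k in 2:8) mu[k + 1] <- (k - 1) * mu[k - 1]
  expect_equal(raw_moments(gn, 8)$values, mu)

  # beta and gamma against numeric integration
  be <- random_input("beta", shape1 = 2, shape2 = 5)
  for (k in 1:4)
    expect_equal(raw_moments(be, k)$values[k + 1],
                 integrate(function(x) x^k * dbeta(x, 2, 5), 0, 1,
                           rel.tol = 1e-12)$value, tolerance = 1e-9)
  ga <- random_input("gamma", shape = 3, rate = 2)
  expect_equal(raw_moments(ga, 3)$values, c(1, 3/2, 3, 15/2))

  s <- random_input("samples", x = c(1, 2, 3, 4))
  expect_equal(raw_moments(s, 2)$values, c(1, 2.5, 7.5))

  mseq <- random_input("moments", mu = c(1, 0, 1, 0, 3))
  expect_equal(raw_moments(mseq, 4)$values, c(1, 0, 1, 0, 3))
  expect_error(raw_moments(mseq, 6), "exceeds")
})

test_that("invalid input specifications are rejected", {
  expect_error(random_input("uniform", lower = 1, upper = 1), "upper > lower")
  expect_error(random_input("gaussian", sd = 0), "sd > 0")
  expect_error(random_input("samples", x = c(2, 2)), "variance")
  expect_error(random_input("samples", x = 3), "at least 2")
  expect_error(random_input("moments", mu = c(2, 0, 1)), "mu0")
  # Hankel [1, 0; 0, -1] is indefinite: no generating measure
  expect_error(random_input("moments", mu = c(1, 0, -1)), "positive semidefinite")
  expect_error(random_input("discrete", values = 1:2, probs = c(0.7, 0.7)),
               "summing to 1")
})

test_that("monic Hankel solve matches hand-derived and oracle polynomials", {
  u <- random_input("uniform", lower = -1, upper = 1)
  mt <- raw_moments(u, 9)
  b <- monic_orthogonal_basis(mt, 3)
  expect_equal(b$monic[[1]], 1)
  expect_equal(b$monic[[2]], c(0, 1))            # zero mean forces xi
  expect_equal(b$monic[[3]], c(-1/3, 0, 1))      # hand-solved 3x3 system
  # leading coefficients are exactly 1
  for (k in 0:3) expect_identical(b$monic[[k + 1]][k + 1], 1)

  gn <- random_input("gaussian")
  bg <- monic_orthogonal_basis(raw_moments(gn, 9), 3)
  expect_equal(bg$monic[[4]], c(0, -3, 0, 1))    # probabilists' He_3

  # Gram-Schmidt oracle under the same measure, r <= 5, several input kinds
  set.seed(11)
  kinds <- list(u, gn, random_input("beta", shape1 = 2, shape2 = 5),
                random_input("samples", x = runif(2000)))
  for (inp in kinds) {
    mu <- raw_moments(inp, 11)$values
    m1 <- mu[2]; s1 <- sqrt(mu[3] - mu[2]^2)
    # compare in standardised coordinates, where the package solves Eq-style
    # Hankel systems; the oracle is plain Gram-Schmidt on monomials
    mu_std <- netres:::affine_moments(mu, -m1 / s1, 1 / s1)
    mt_std <- structure(list(max_order = 11L, values = mu_std),
                        class = "moment_table")
    bb <- monic_orthogonal_basis(mt_std, 5)
    orc <- oracle_gram_schmidt(mu_std, 5)
    for (k in 0:5)
      expect_equal(bb$monic[[k + 1]], orc[[k + 1]], tolerance = 1e-8)
  }
})

test_that("ill-conditioned or degenerate moment systems fail loudly", {
  two_atoms <- random_input("discrete", values = c(-1, 1))
  mt <- raw_moments(two_atoms, 9)
  expect_error(monic_orthogonal_basis(mt, 3), "ill-conditioned")
  expect_error(apc_basis(random_input("discrete", values = 1, probs = 1), 2),
               "degenerate")
  expect_error(monic_orthogonal_basis(raw_moments(two_atoms, 3), 10),
               "moments up to")
})

test_that("orthonormalization yields unit norms and the expected low orders", {
  u <- random_input("uniform", lower = -1, upper = 1)
  b <- apc_basis(u, 2)
  expect_equal(b$coef[[1]], 1)                       # constant 1
  expect_equal(b$coef[[2]], c(0, sqrt(3)))           # sqrt(3) xi
  gn <- random_input("gaussian")
  bg <- apc_basis(gn, 2)
  expect_equal(bg$coef[[3]], c(-1, 0, 1) / sqrt(2))  # (xi^2 - 1)/sqrt(2)
  # positive leading coefficient convention
  for (k in 0:2) expect_gt(b$coef[[k + 1]][k + 1], 0)
})

test_that("multi-index sets have the right count and graded order", {
  expect_equal(multi_index_set(2, 3)$Z, 10)
  expect_equal(multi_index_set(1, 4)$Z, 5)
  mis <- multi_index_set(3, 0)
  expect_equal(mis$Z, 1)
  expect_equal(mis$indices[1, ], c(0L, 0L, 0L))
  for (l in 1:5)
    for (r in 0:5) {
      m <- multi_index_set(l, r)
      expect_equal(m$Z, choose(l + r, r))
      expect_equal(nrow(unique(m$indices)), m$Z)
      expect_true(!is.unsorted(rowSums(m$indices)))  # graded
      expect_true(all(rowSums(m$indices) <= r))
    }
})

test_that("multivariate basis evaluates as products of univariate factors", {
  u <- function() random_input("uniform", lower = -1, upper = 1)
  mb <- multivariate_basis(list(u(), u()), 2)
  expect_equal(evaluate_basis(mb, c(0.3, -0.8), 1), 1)    # constant
  i11 <- which(apply(mb$index_set$indices, 1, identical, c(1L, 1L)))
  expect_equal(evaluate_basis(mb, c(1, 1), i11), 3)       # sqrt(3)*sqrt(3)
  expect_error(evaluate_basis(mb, c(1, 2, 3), 2), "coordinates")

  # Monte Carlo Gram close to identity under the product measure
  set.seed(4)
  n <- 1e5
  pts <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  Phi <- netres:::evaluate_basis_matrix(mb, pts)
  G <- crossprod(Phi) / n
  expect_lt(max(abs(G - diag(mb$Z))), 0.03)
})

test_that("Gauss rules hit known nodes and integrate exactly to degree 2n-1", {
  q <- quadrature_rule(random_input("gaussian"), 2)
  expect_equal(q$nodes, c(-1, 1))
  expect_equal(q$weights, c(0.5, 0.5))
  q <- quadrature_rule(random_input("uniform", lower = -1, upper = 1), 2)
  expect_equal(q$nodes, c(-1, 1) / sqrt(3))
  expect_equal(q$weights, c(0.5, 0.5))
  # one node: the mean, weight one
  g <- random_input("gamma", shape = 3, rate = 2)
  q1 <- quadrature_rule(g, 1)
  expect_equal(q1$nodes, 1.5)
  expect_equal(q1$weights, 1)

  set.seed(21)
  kinds <- list(random_input("uniform", lower = 0.9, upper = 1.1),
                random_input("gaussian", mean = 2, sd = 0.5),
                random_input("beta", shape1 = 2, shape2 = 5),
                g,
                random_input("samples", x = rnorm(5000)),
                random_input("moments", mu = c(1, 0, 1, 0, 3, 0, 15, 0, 105)))
  for (inp in kinds)
    for (n in c(2L, 4L)) {
      q <- quadrature_rule(inp, n)
      expect_true(all(q$weights > 0))
      expect_equal(sum(q$weights), 1, tolerance = 1e-12)
      mu <- raw_moments(inp, 2L * n - 1L)$values
      for (k in seq_len(2L * n - 1L))
        expect_equal(sum(q$weights * q$nodes^k), mu[k + 1],
                     tolerance = 1e-7 * max(1, abs(mu[k + 1])))
    }
  expect_error(quadrature_rule(random_input("discrete", values = c(0, 1)), 3),
               "ill-conditioned|positive")
})

test_that("standardisation makes far-from-origin supports workable", {
  shifted <- random_input("uniform", lower = 100, upper = 100.2)
  b <- apc_basis(shifted, 5)
  # Gram via substitution u = (x - 100)/0.2, u ~ U[0, 1]
  G <- matrix(0, 6, 6)
  for (i in 0:5)
    for (j in i:5) {
      v <- integrate(function(u)
        eval_basis_poly(b, 100 + 0.2 * u, i) *
          eval_basis_poly(b, 100 + 0.2 * u, j),
        0, 1, rel.tol = 1e-11)$value
      G[i + 1, j + 1] <- v; G[j + 1, i + 1] <- v
    }
  expect_lt(max(abs(G - diag(6))), 1e-6)
})
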