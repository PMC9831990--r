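# Shared fixtures, built in code at test time.

# Case-study parameter set (homogeneous, deterministic)
fix_model <- function() mutualistic_model()

# Case-A uncertainty: C and E within 10% of their means, uniform, shared
fix_case_a_model <- function() {
  mutualistic_model(
    C = random_input("uniform", lower = 0.9, upper = 1.1, label = "C"),
    E = random_input("uniform", lower = 0.81, upper = 0.99, label = "E"))
}

fix_case_a_inputs <- function() {
  m <- fix_case_a_model()
  m$params[c("C", "E")]
}

# medium random graph at a prescribed average weight
fix_graph <- function(N = 40L, w_av = 6.9, seed = 42L) {
  generate_network(network_recipe("erdos-renyi", N = N, density = 0.2,
                                  weight = "uniform", target_w_av = w_av,
                                  seed = seed))
}

# graph whose node 1 is marginal: a single in-edge at the deterministic
# critical in-weight, the regime where uncertainty decides node resilience
fix_vulnerable_graph <- function(N = 40L, w_av = 6.9, seed = 42L) {
  g <- fix_graph(N, w_av, seed)
  M <- g$M
  M[, 1] <- 0
  g1 <- weighted_digraph(M)
  # marginal in the sequential-estimation convention: neighbour state is the
  # largest mean-field root, and node 1's single in-edge sits at the
  # in-weight where its indicator crosses zero
  mod <- fix_model()
  p <- resolve_params(mod)
  x_e0 <- healthy_equilibrium(mod, g1)$x_e0
  wc <- netres:::node_wcrit_(mod, p, x_e0, w_in_max = 5, tol = 1e-8)
  M[2, 1] <- wc
  weighted_digraph(M)
}

# independent Gram-Schmidt construction of monic orthogonal polynomials
# from raw moments (a different algorithm than the Hankel solve)
oracle_gram_schmidt <- function(mu, r) {
  inner <- function(a, b) {
    out <- 0
    for (i in seq_along(a))
      for (j in seq_along(b))
        out <- out + a[i] * b[j] * mu[i + j - 1L]
    out
  }
  polys <- list(1)
  if (r >= 1L) {
    for (k in 1:r) {
      p <- c(numeric(k), 1)           # x^k
      for (q in seq_len(k)) {
        pq <- polys[[q]]
        coef_proj <- inner(p, pq) / inner(pq, pq)
        p[seq_along(pq)] <- p[seq_along(pq)] - coef_proj * pq
      }
      polys[[k + 1L]] <- p
    }
  }
  polys
}

# orthonormal probabilists' Hermite coefficients (ascending), degree k
oracle_hermite <- function(k) {
  He <- list(1, c(0, 1))
  if (k >= 2L)
    for (j in 2:k) {
      prev <- He[[j]]; prev2 <- He[[j - 1L]]
      p <- c(0, prev)                              # x * He_{j-1}
      p[seq_along(prev2)] <- p[seq_along(prev2)] - (j - 1) * prev2
      He[[j + 1L]] <- p
    }
  He[[k + 1L]] / sqrt(factorial(k))
}

# orthonormal Legendre coefficients on [-1, 1] (ascending), degree k
oracle_legendre <- function(k) {
  P <- list(1, c(0, 1))
  if (k >= 2L)
    for (j in 2:k) {
      prev <- P[[j]]; prev2 <- P[[j - 1L]]
      p <- c(0, prev) * (2 * j - 1) / j
      p[seq_along(prev2)] <- p[seq_along(prev2)] - (j - 1) / j * prev2
      P[[j + 1L]] <- p
    }
  P[[k + 1L]] * sqrt(2 * k + 1)
}

# numeric-quadrature Gram matrix of an orthonormal basis under a named
# density (independent of the package's own quadrature machinery)
oracle_gram <- function(basis, dens, lower, upper) {
  r <- basis$max_degree
  G <- matrix(0, r + 1L, r + 1L)
  for (i in 0:r)
    for (j in i:r) {
      v <- stats::integrate(function(x)
        eval_basis_poly(basis, x, i) * eval_basis_poly(basis, x, j) * dens(x),
        lower, upper, rel.tol = 1e-10, abs.tol = 1e-10,
        subdivisions = 500L)$value
      G[i + 1L, j + 1L] <- v; G[j + 1L, i + 1L] <- v
    }
  G
}
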