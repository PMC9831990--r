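#' Monic orthogonal polynomials from raw moments
#'
#' Builds the monic orthogonal polynomial family of degrees `0..r` for the
#' measure behind a raw moment table, by solving for each degree \eqn{k} the
#' (k+1)-dimensional Hankel linear system that enforces orthogonality of the
#' monic degree-k polynomial to all lower powers.  This is the defining
#' construction of arbitrary polynomial chaos: the data enter only through
#' raw moments.
#'
#' The Hankel system is notoriously ill-conditioned in raw coordinates;
#' callers wanting a numerically safe basis for a concrete input should use
#' [apc_basis()], which standardises to zero mean / unit variance first.
#'
#' @param moments a `moment_table` from [raw_moments()], with
#'   `max_order >= 2*r - 1`.
#' @param r maximum polynomial degree.
#' @param cond_tol reject systems with condition number above this.
#' @return an object of class `univariate_basis` with the monic coefficient
#'   triangle (`monic[[k+1]]` = ascending coefficients of the degree-k
#'   polynomial, leading coefficient 1); not yet orthonormal.
#' @export
monic_orthogonal_basis <- function(moments, r, cond_tol = 1e12) {
  stopifnot(inherits(moments, "moment_table"), r >= 0)
  r <- as.integer(r)
  if (r > 10L) stop("degrees above r = 10 are not supported (moment determinacy)")
  if (moments$max_order < max(2L * r - 1L, 0L))
    stop("need moments up to order ", 2L * r - 1L,
         ", have ", moments$max_order)
  mu <- moments$values
  monic <- vector("list", r + 1L)
  monic[[1]] <- 1
  if (r >= 1L) {
    for (k in 1:r) {
      A <- matrix(0, k + 1L, k + 1L)
      for (i in 1:k) A[i, ] <- mu[(i - 1L) + seq_len(k + 1L)]
      A[k + 1L, k + 1L] <- 1
      kap <- kappa(A, exact = TRUE)
      if (!is.finite(kap) || kap > cond_tol)
        stop(sprintf(
          "Hankel system for degree %d is ill-conditioned (condition number %.3g > %.3g); the input may have fewer than %d support atoms or needs standardisation",
          k, kap, cond_tol, k + 1L))
      rhs <- c(numeric(k), 1)
      monic[[k + 1L]] <- solve(A, rhs)
    }
  }
  structure(list(max_degree = r, monic = monic, coef = NULL, norms = NULL,
                 orthonormal = FALSE, transform = c(mean = 0, sd = 1)),
            class = "univariate_basis")
}

basis_norms <- function(monic, mu) {
  vapply(monic, function(cf) {
    k <- length(cf)
    H <- outer(seq_len(k), seq_len(k), function(i, j) mu[i + j - 1L])
    v <- drop(crossprod(cf, H %*% cf))
    if (v <= 0) stop("zero or negative polynomial norm: degenerate measure")
    sqrt(v)
  }, 0)
}

#' Orthonormalize a monic basis
#'
#' Divides each monic polynomial by its norm under the input measure; the
#' sign convention is a positive leading coefficient (automatic, since norms
#' are positive).
#'
#' @param basis a `univariate_basis` from [monic_orthogonal_basis()].
#' @param moments the same measure's `moment_table`, with
#'   `max_order >= 2 * basis$max_degree`.
#' @return the basis with `coef` (orthonormal coefficients) and `norms`
#'   filled in and `orthonormal = TRUE`.
#' @export
orthonormalize <- function(basis, moments) {
  stopifnot(inherits(basis, "univariate_basis"), inherits(moments, "moment_table"))
  r <- basis$max_degree
  if (moments$max_order < 2L * r)
    stop("need moments up to order ", 2L * r, " to compute norms")
  nrm <- basis_norms(basis$monic, moments$values)
  basis$norms <- nrm
  basis$coef <- Map(function(cf, s) cf / s, basis$monic, nrm)
  basis$orthonormal <- TRUE
  basis
}

#' Orthonormal aPC basis for a random input
#'
#' End-to-end construction: the input is standardised to zero mean and unit
#' variance (the Hankel moment system is severely ill-conditioned in raw
#' coordinates), the monic family is built from standardised moments and
#' orthonormalised, and the polynomials are mapped back to the original
#' variable.  For a Gaussian input the result is the normalised
#' probabilists' Hermite family; for a uniform input, the normalised
#' Legendre family shifted to the support.
#'
#' @inheritParams monic_orthogonal_basis
#' @param input a [random_input()].
#' @return orthonormal `univariate_basis` in the original variable;
#'   `coef[[k+1]]` are ascending coefficients of the degree-k polynomial.
#' @examples
#' b <- apc_basis(random_input("gaussian"), 3)
#' b$coef[[4]]  # (xi^3 - 3 xi)/sqrt(6)
#' @export
apc_basis <- function(input, r, cond_tol = 1e12) {
  stopifnot(is_random_input(input))
  r <- as.integer(r)
  need <- max(2L * r, 2L)
  m1 <- ri_mean(input)
  s <- ri_sd(input)
  if (s <= 0) stop("degenerate (zero-variance) input: no orthonormal basis")
  mu_std <- standardized_moments(input, need)
  mt_std <- structure(list(max_order = need, values = mu_std),
                      class = "moment_table")
  b <- monic_orthogonal_basis(mt_std, r, cond_tol = cond_tol)
  b <- orthonormalize(b, mt_std)
  # standardised-variable coefficients are kept for evaluation (expanding
  # q_k((x - m)/s) into monomials of x is catastrophically ill-conditioned
  # for supports far from the origin); the expanded original-variable
  # coefficients are exposed for inspection and closed-form comparisons
  b$coef_std <- b$coef
  b$monic_std <- b$monic
  b$coef <- lapply(b$coef, poly_affine_compose, s = -m1 / s, t = 1 / s)
  b$monic <- lapply(seq_along(b$monic), function(i) {
    # s^k * q_k((xi-m1)/s) stays monic in xi
    s^(i - 1L) * poly_affine_compose(b$monic[[i]], s = -m1 / s, t = 1 / s)
  })
  b$norms <- b$norms * s^(seq_len(r + 1L) - 1L)
  b$transform <- c(mean = m1, sd = s)
  b$input <- input
  b
}

#' Evaluate one polynomial of a univariate basis
#'
#' @param basis a `univariate_basis` (orthonormal unless `monic = TRUE`).
#' @param x evaluation points.
#' @param degree polynomial degree, `0..max_degree`.
#' @param monic evaluate the monic rather than the orthonormal polynomial.
#' @return numeric vector of values.
#' @export
eval_basis_poly <- function(basis, x, degree, monic = FALSE) {
  stopifnot(degree >= 0, degree <= basis$max_degree)
  if (!is.null(basis$coef_std)) {
    # numerically stable: evaluate in standardised coordinates
    z <- (x - basis$transform[["mean"]]) / basis$transform[["sd"]]
    if (monic)
      return(basis$transform[["sd"]]^degree *
               polyval(basis$monic_std[[degree + 1L]], z))
    return(polyval(basis$coef_std[[degree + 1L]], z))
  }
  cf <- if (monic) basis$monic[[degree + 1L]] else {
    if (!basis$orthonormal) stop("basis is not orthonormal; use monic = TRUE")
    basis$coef[[degree + 1L]]
  }
  polyval(cf, x)
}

#' Graded multi-index set of total degree at most r
#'
#' Enumerates all length-`l` tuples of non-negative integers with sum at
#' most `r`, in graded lexicographic order.  Their count is
#' \eqn{Z = (l+r)!/(l!\,r!)}, the dimension of the total-degree-`r`
#' polynomial space in `l` variables.
#'
#' @param l number of variables (>= 1).
#' @param r total-degree cap (>= 0).
#' @return object of class `multi_index_set`: fields `l`, `r`, `Z`, and
#'   `indices` (a `Z x l` integer matrix, one tuple per row; row 1 is the
#'   all-zero tuple).
#' @export
multi_index_set <- function(l, r) {
  stopifnot(l >= 1, r >= 0)
  l <- as.integer(l); r <- as.integer(r)
  comps <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- lapply(total:0, function(first)
      cbind(first, comps(total - first, parts - 1L)))
    do.call(rbind, out)
  }
  idx <- do.call(rbind, lapply(0:r, comps, parts = l))
  dimnames(idx) <- NULL
  structure(list(l = l, r = r, Z = nrow(idx), indices = idx),
            class = "multi_index_set")
}

#' Multivariate orthonormal basis over independent inputs
#'
#' Tensor-product basis \eqn{\Phi_i(\xi) = \prod_j P_j^{(\alpha_j^i)}(\xi_j)}
#' over the graded multi-index set of total degree at most `r`; valid for
#' independent inputs, under whose product measure the family is
#' orthonormal.
#'
#' @param inputs list of [random_input()] objects (length `l`).
#' @param r total-degree cap.
#' @return object of class `multivariate_basis` with per-variable univariate
#'   bases, the `multi_index_set`, and `Z`.
#' @export
multivariate_basis <- function(inputs, r) {
  stopifnot(length(inputs) >= 1L, all(vapply(inputs, is_random_input, TRUE)))
  uni <- lapply(inputs, apc_basis, r = r)
  mis <- multi_index_set(length(inputs), r)
  structure(list(l = mis$l, r = as.integer(r), Z = mis$Z,
                 univariate = uni, index_set = mis, inputs = inputs),
            class = "multivariate_basis")
}

#' Evaluate one multivariate basis polynomial
#'
#' `index` is 1-based: `index = 1` is the constant polynomial
#' \eqn{\Phi \equiv 1} (all-zero multi-index).
#'
#' @param mbasis a [multivariate_basis()].
#' @param point numeric vector of length `l` (or matrix with `l` columns,
#'   one point per row).
#' @param index which basis polynomial, `1..Z`.
#' @return numeric value(s).
#' @export
evaluate_basis <- function(mbasis, point, index) {
  stopifnot(inherits(mbasis, "multivariate_basis"),
            index >= 1, index <= mbasis$Z)
  if (is.null(dim(point))) point <- matrix(point, nrow = 1L)
  if (ncol(point) != mbasis$l)
    stop("point has ", ncol(point), " coordinates; basis needs ", mbasis$l)
  alpha <- mbasis$index_set$indices[index, ]
  out <- rep(1, nrow(point))
  for (j in seq_len(mbasis$l))
    out <- out * eval_basis_poly(mbasis$univariate[[j]], point[, j], alpha[j])
  drop(out)
}

# n x Z design matrix of all basis polynomials at the given points
evaluate_basis_matrix <- function(mbasis, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = mbasis$l)
  # precompute univariate values per variable and degree
  vals <- lapply(seq_len(mbasis$l), function(j)
    vapply(0:mbasis$r, function(d)
      eval_basis_poly(mbasis$univariate[[j]], points[, j], d),
      numeric(nrow(points))))
  out <- matrix(1, nrow(points), mbasis$Z)
  idx <- mbasis$index_set$indices
  for (i in seq_len(mbasis$Z))
    for (j in seq_len(mbasis$l))
      out[, i] <- out[, i] * vals[[j]][, idx[i, j] + 1L]
  out
}

#' Gauss quadrature rule for an arbitrary input
#'
#' Nodes and weights of the n-point Gauss rule for the input's measure,
#' obtained from the Jacobi (tridiagonal) matrix of three-term recurrence
#' coefficients of the standardised monic orthogonal family
#' (Golub--Welsch).  Exact for polynomials of degree `2n - 1`.
#'
#' @param input a [random_input()].
#' @param n_nodes number of nodes (>= 1).
#' @return list with `nodes` and `weights` (weights positive, summing to 1).
#' @export
quadrature_rule <- function(input, n_nodes) {
  stopifnot(is_random_input(input), n_nodes >= 1)
  n <- as.integer(n_nodes)
  m1 <- ri_mean(input); s <- ri_sd(input)
  if (s <= 0) {
    if (n == 1L) return(list(nodes = m1, weights = 1))
    stop("degenerate (zero-variance) input supports only a 1-node rule")
  }
  if (n == 1L) return(list(nodes = m1, weights = 1))
  rec <- recurrence_coefficients(input, n)
  alpha <- rec$alpha
  beta <- rec$beta[-1L]
  J <- diag(alpha, n, n)
  if (n >= 2L) {
    sb <- sqrt(beta)
    J[cbind(1:(n - 1L), 2:n)] <- sb
    J[cbind(2:n, 1:(n - 1L))] <- sb
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  z <- e$values[ord]
  w <- e$vectors[1L, ord]^2
  w <- w / sum(w)
  list(nodes = z, weights = w)
}

# Monic three-term recurrence p_{k+1} = (x - alpha_k) p_k - beta_k p_{k-1}
# in the ORIGINAL variable.  Closed forms (Gautschi) for named families;
# Cholesky of the standardised Hankel moment matrix for data-driven inputs,
# where only moderate orders are meaningful anyway.
recurrence_coefficients <- function(input, n) {
  s <- input$spec
  k <- seq_len(n) - 1      # 0 .. n-1
  out <- switch(input$kind,
    gaussian = list(alpha = rep(s$mean, n), beta = c(1, k[-1L] * s$sd^2)),
    uniform = {
      c0 <- (s$lower + s$upper) / 2; h <- (s$upper - s$lower) / 2
      kk <- k[-1L]
      list(alpha = rep(c0, n), beta = c(1, h^2 * kk^2 / (4 * kk^2 - 1)))
    },
    beta = {
      # Jacobi weight (1-x)^a (1+x)^b on [-1,1] with a = shape2-1, b = shape1-1
      a <- s$shape2 - 1; b <- s$shape1 - 1
      al <- vapply(k, function(j) {
        if (j == 0) (b - a) / (a + b + 2)
        else (b^2 - a^2) / ((2 * j + a + b) * (2 * j + a + b + 2))
      }, 0)
      be <- vapply(k, function(j) {
        if (j == 0) 1
        else if (j == 1) 4 * (1 + a) * (1 + b) / ((2 + a + b)^2 * (3 + a + b))
        else 4 * j * (j + a) * (j + b) * (j + a + b) /
          ((2 * j + a + b)^2 * (2 * j + a + b + 1) * (2 * j + a + b - 1))
      }, 0)
      c0 <- (s$lower + s$upper) / 2; h <- (s$upper - s$lower) / 2
      list(alpha = c0 + h * al, beta = c(1, h^2 * be[-1L]))
    },
    gamma = {
      a <- s$shape - 1
      list(alpha = (2 * k + a + 1) / s$rate,
           beta = c(1, (k[-1L] * (k[-1L] + a)) / s$rate^2))
    },
    { # discrete, samples, moments: standardised moment-matrix Cholesky
      m1 <- ri_mean(input); sd1 <- ri_sd(input)
      mu <- standardized_moments(input, 2L * n)
      H <- outer(seq_len(n + 1L), seq_len(n + 1L),
                 function(i, j) mu[i + j - 1L])
      R <- tryCatch(chol(H), error = function(e)
        stop("ill-conditioned recurrence: moment matrix is not positive ",
             "definite (input may have fewer than ", n, " support atoms)"))
      rr <- diag(R)
      off <- R[cbind(seq_len(n), seq_len(n) + 1L)]
      alpha_z <- off / rr[seq_len(n)] -
        c(0, off[seq_len(n - 1L)] / rr[seq_len(n - 1L)])
      beta_z <- (rr[2:n] / rr[1:(n - 1L)])^2
      list(alpha = m1 + sd1 * alpha_z, beta = c(1, sd1^2 * beta_z))
    })
  out
}
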