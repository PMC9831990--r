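# Small dense-polynomial helpers. Coefficients are ascending: c[1] + c[2]*x + ...

polyval <- function(coef, x) {
  # Horner, vectorised over x
  r <- rep(coef[length(coef)], length(x))
  if (length(coef) > 1L) {
    for (k in seq(length(coef) - 1L, 1L)) r <- r * x + coef[k]
  }
  r
}

poly_trim <- function(coef, tol = 0) {
  n <- length(coef)
  while (n > 1L && abs(coef[n]) <= tol) n <- n - 1L
  coef[seq_len(n)]
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Coefficients of q(s + t*x) given coefficients of q(z)
poly_affine_compose <- function(coef, s, t) {
  out <- coef[1]
  lin <- c(s, t)
  pw <- 1
  for (k in seq_along(coef)[-1]) {
    pw <- poly_mult(pw, lin)
    n <- max(length(out), length(pw))
    out <- c(out, numeric(n - length(out)))
    out[seq_along(pw)] <- out[seq_along(pw)] + coef[k] * pw
  }
  out
}
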