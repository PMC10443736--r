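## Gauss-Jacobi quadrature on [0, 1] for integrands with Beta-type
## endpoint behaviour  t^p (1-t)^q f(t),  p, q > -1,  f smooth.
##
## Nodes and weights come from the Golub-Welsch eigenvalue method applied
## to the three-term recurrence of the Jacobi polynomials P^(A,B) with
## weight (1-x)^A (1+x)^B on [-1, 1]; A corresponds to the exponent at
## t = 1 and B to the exponent at t = 0 after the affine map t = (1+x)/2.
## Every diffusion integral in the package factors its integrand as
## (Beta kernel) x (smooth exponential), so a modest fixed node count
## integrates the smooth factor to machine precision.

#' Gauss--Jacobi rule on the unit interval
#'
#' Returns nodes `t` in `(0, 1)` and weights `w` such that
#' `sum(w * f(t))` approximates `integral_0^1 t^p (1-t)^q f(t) dt`
#' exactly for polynomials `f` up to degree `2n - 1`.
#'
#' @param n Number of nodes.
#' @param p Exponent of `t` at the left endpoint (> -1).
#' @param q Exponent of `1 - t` at the right endpoint (> -1).
#' @return A list with numeric vectors `t` and `w`.
#' @examples
#' r <- gauss_jacobi(20, -0.3, -0.5)
#' sum(r$w)            # equals beta(0.7, 0.5)
#' @export
gauss_jacobi <- function(n, p, q) {
  stopifnot(n >= 1, p > -1, q > -1)
  A <- q  # exponent on (1 - x) after mapping
  B <- p  # exponent on (1 + x)
  k <- seq_len(n) - 1          # 0 .. n-1
  s <- 2 * k + A + B
  ## diagonal (recurrence alpha_k); k = 0 written directly to avoid the
  ## 0/0 that the generic form hits when A + B = 0
  diag_ab <- (B^2 - A^2) / (s * (s + 2))
  diag_ab[1] <- (B - A) / (A + B + 2)
  if (n > 1) {
    k1 <- seq_len(n - 1)       # 1 .. n-1
    s1 <- 2 * k1 + A + B
    b2 <- 4 * k1 * (k1 + A) * (k1 + B) * (k1 + A + B) /
      (s1^2 * (s1 + 1) * (s1 - 1))
    ## k = 1 term when A + B = -1 needs the direct formula
    if (abs(A + B + 1) < .Machine$double.eps * 4)
      b2[1] <- 4 * (1 + A) * (1 + B) / ((2 + A + B)^2 * (3 + A + B))
    offd <- sqrt(b2)
  } else offd <- numeric(0)
  J <- diag(diag_ab, n, n)
  if (n > 1) {
    J[cbind(k1, k1 + 1)] <- offd
    J[cbind(k1 + 1, k1)] <- offd
  }
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  mu0 <- 2^(A + B + 1) * beta(A + 1, B + 1)
  w <- mu0 * rev(e$vectors[1, ])^2
  ## map [-1, 1] -> [0, 1]:  t = (1+x)/2, weight picks up 2^{-(p+q+1)}
  list(t = (1 + x) / 2, w = w / 2^(p + q + 1))
}

## integral_0^1 t^p (1-t)^q f(t) dt with a smooth vectorised f.
beta_kernel_integral <- function(f, p, q, n = 80) {
  r <- gauss_jacobi(n, p, q)
  sum(r$w * f(r$t))
}

## integral_0^lo.. 0^upper t^p (1-t)^q f(t) dt for upper in (0, 1]:
## substitute t = upper * s so only the left singularity remains active.
beta_kernel_integral_partial <- function(f, p, q, upper, n = 80) {
  if (upper >= 1) return(beta_kernel_integral(f, p, q, n))
  r <- gauss_jacobi(n, p, 0)
  t <- upper * r$t
  upper^(p + 1) * sum(r$w * (1 - t)^q * f(t))
}
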