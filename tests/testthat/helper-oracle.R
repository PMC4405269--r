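# Independent numerical oracle for the partition Bayes factor.
#
# Opposite integration order to the closed form: the scale matrix Sigma is
# integrated analytically (inverse-Wishart integral) GIVEN the genotype
# effect row b, and the remaining |D|-dimensional integral over b is done by
# Gauss-Legendre quadrature after a tangent substitution mapping the real
# line to a finite interval (the integrand has polynomial tails). Supports
# |D| <= 2, which is enough to exercise every structural element of the
# closed form (covariate projection, Wishart degrees, rank-1 updates).

lgamma_k <- function(a, k) {
  k * (k - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(k)) / 2))
}

log10_bf_oracle <- function(Y, g, partition, sigma_a, n_nodes = 301) {
  U <- which(partition == "U")
  D <- which(partition == "D")
  k <- length(D)
  n <- nrow(Y)
  W <- cbind(1, Y[, U, drop = FALSE])
  q <- ncol(W)
  nu <- n - q
  qrW <- qr(W)
  Yt <- qr.resid(qrW, Y[, D, drop = FALSE])
  gt <- qr.resid(qrW, g)
  R0 <- crossprod(Yt)
  u <- drop(crossprod(Yt, gt))
  a <- sum(gt^2) + 1 / sigma_a^2
  bhat <- u / a
  scl <- sqrt(diag(R0) / nu / a) * 3
  gl <- pracma::gaussLegendre(n_nodes, -pi / 2 + 1e-12, pi / 2 - 1e-12)
  ex <- -(nu + 1) / 2
  if (k == 1) {
    b <- bhat + scl * tan(gl$x)
    lf <- ex * log(R0[1, 1] + a * b^2 - 2 * u * b) +
      log(scl) - 2 * log(cos(gl$x))
    mx <- max(lf)
    logI <- mx + log(sum(gl$w * exp(lf - mx)))
  } else if (k == 2) {
    b1 <- bhat[1] + scl[1] * tan(gl$x)
    b2 <- bhat[2] + scl[2] * tan(gl$x)
    jac1 <- log(scl[1]) - 2 * log(cos(gl$x))
    jac2 <- log(scl[2]) - 2 * log(cos(gl$x))
    B1 <- matrix(b1, n_nodes, n_nodes)
    B2 <- matrix(b2, n_nodes, n_nodes, byrow = TRUE)
    S11 <- R0[1, 1] + a * B1^2 - 2 * u[1] * B1
    S22 <- R0[2, 2] + a * B2^2 - 2 * u[2] * B2
    S12 <- R0[1, 2] + a * B1 * B2 - u[1] * B2 - u[2] * B1
    lf <- ex * log(S11 * S22 - S12^2) + outer(jac1, jac2, "+")
    mx <- max(lf)
    logI <- mx + log(sum(outer(gl$w, gl$w) * exp(lf - mx)))
  } else {
    stop("oracle supports |D| <= 2")
  }
  (-(k / 2) * log(2 * pi * sigma_a^2) + (k / 2) * log(2) +
      lgamma_k((nu + 1) / 2, k) - lgamma_k(nu / 2, k) +
      (nu / 2) * determinant(R0)$modulus + logI) / log(10)
}
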