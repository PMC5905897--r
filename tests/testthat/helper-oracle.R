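# Independent oracles used by the tests. These deliberately do not share
# code with the package internals.

# High-precision accelerated proximal-gradient solver for
#   min ||b - J x||_2^2 + lambda ||x||_1
# (note the full squared data term: gradient 2 J^T (J x - b), prox step
# threshold t * lambda). Run to effective machine precision on the tiny
# instances the tests use.
lasso_oracle <- function(J, b, lambda, iters = 20000) {
  L <- 2 * max(eigen(crossprod(J), symmetric = TRUE, only.values = TRUE)$values)
  t <- 1 / L
  x <- numeric(ncol(J)); xprev <- x; y <- x; a <- 1
  for (i in seq_len(iters)) {
    g <- 2 * drop(crossprod(J, J %*% y - b))
    z <- y - t * g
    xn <- sign(z) * pmax(abs(z) - t * lambda, 0)
    an <- (1 + sqrt(1 + 4 * a^2)) / 2
    y <- xn + ((a - 1) / an) * (xn - x)
    a <- an; xprev <- x; x <- xn
  }
  x
}

lasso_objective <- function(J, b, x, lambda) {
  sum((b - J %*% x)^2) + lambda * sum(abs(x))
}

# 2D infinite-medium Green's function of the diffusion operator for a unit
# point source: phi(r) = K0(mueff r) / (2 pi kappa)
greens_2d <- function(r, mua, musp) {
  kappa <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / kappa)
  besselK(mueff * r, 0) / (2 * pi * kappa)
}

# random small lasso instance with bounded condition number
random_lasso_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:20, 1); p <- sample(4:12, 1)
  J <- matrix(rnorm(n * p), n, p)
  # clamp singular values to condition <= 1e3
  sv <- svd(J)
  d <- pmax(sv$d, max(sv$d) / 1e3)
  J <- sv$u %*% diag(d, length(d)) %*% t(sv$v)
  b <- rnorm(n)
  lambda <- runif(1, 0.1, 0.5) * 2 * max(abs(crossprod(J, b)))
  list(J = J, b = b, lambda = lambda)
}
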