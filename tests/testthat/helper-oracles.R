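# Independent oracles used to cross-check the Laplace engine. These never
# call the package's likelihood code: the linear-Gaussian marginal is a
# closed form, and the quadrature oracle integrates each subject's
# likelihood with adaptive Gauss-Hermite nodes.

# Closed-form -2 log marginal likelihood for subjects with
# y = a + b * eta + e, e ~ N(0, sig_add^2 I), eta ~ N(0, omega2).
oracle_ofv_lingauss <- function(subjects, omega2, sig_add) {
  total <- 0
  for (s in subjects) {
    n <- length(s$y)
    Sigma <- diag(sig_add^2, n) + omega2 * tcrossprod(s$b)
    r <- s$y - s$a
    total <- total + as.numeric(determinant(2 * pi * Sigma)$modulus) +
      as.numeric(t(r) %*% solve(Sigma, r))
  }
  total
}

# Adaptive Gauss-Hermite -2 log marginal likelihood for subjects with an
# arbitrary prediction function f(eta) (1 or 2 random effects, diagonal or
# full omega), proportional + additive residual error.
oracle_ofv_agh <- function(subjects, omega, sigma, n_nodes = 21) {
  gh <- pracma::gaussHermite(n_nodes)
  q <- nrow(omega)
  oinv <- solve(omega)
  ldo <- as.numeric(determinant(omega)$modulus)
  neg_log_joint <- function(s, eta) {
    f <- s$f(eta)
    g2 <- (sigma[["prop"]] * f)^2 + sigma[["add"]]^2
    0.5 * sum((s$y - f)^2 / g2 + log(2 * pi * g2)) +
      0.5 * as.numeric(t(eta) %*% oinv %*% eta) +
      0.5 * (ldo + q * log(2 * pi))
  }
  total <- 0
  for (s in subjects) {
    opt <- nlminb(numeric(q), function(e) neg_log_joint(s, e))
    m <- opt$par
    H <- optimHess(m, function(e) neg_log_joint(s, e))
    L <- t(chol(solve(H)))
    if (q == 1) {
      vals <- vapply(seq_len(n_nodes), function(k) {
        eta <- m + sqrt(2) * L[1, 1] * gh$x[k]
        gh$w[k] * exp(gh$x[k]^2 - neg_log_joint(s, eta))
      }, 0)
      Li <- sqrt(2) * L[1, 1] * sum(vals)
    } else {
      acc <- 0
      for (j in seq_len(n_nodes)) {
        for (k in seq_len(n_nodes)) {
          x <- c(gh$x[j], gh$x[k])
          eta <- m + sqrt(2) * as.numeric(L %*% x)
          acc <- acc + gh$w[j] * gh$w[k] *
            exp(sum(x^2) - neg_log_joint(s, eta))
        }
      }
      Li <- 2 * det(L) * acc
    }
    total <- total - 2 * log(Li)
  }
  total
}
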