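# Shared fixtures: small random designs, closed-form oracles, and
# exhaustive-enumeration helpers. All randomness is seeded locally.

rand_design <- function(N, R = 2, seed = NULL, center_x = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  g <- rnorm(N)
  if (center_x) g <- g - mean(g)
  M <- if (R == 2) cbind(g, 1) else cbind(g, matrix(rnorm(N * (R - 2)), N), 1)
  list(M = M, C = c(1, rep(0, R - 1)))
}

# Closed-form GLM oracle: t statistic for C'psi from the normal equations.
oracle_t <- function(Y, M, C) {
  Y <- as.matrix(Y)
  MtM <- crossprod(M)
  psi <- solve(MtM, crossprod(M, Y))
  res <- Y - M %*% psi
  df <- nrow(M) - qr(M)$rank
  s2 <- colSums(res^2) / df
  drop(crossprod(C, psi)) / sqrt(s2 * drop(t(C) %*% solve(MtM) %*% C))
}

# Exhaustive moments of trace(A P W P') by enumerating all permutations.
enum_traceAW_moments <- function(A, W) {
  N <- nrow(A)
  perms <- permaccel:::all_perms(N)
  vals <- apply(perms, 1, function(pm) sum(A[pm, pm] * W))
  mu <- mean(vals)
  v <- mean((vals - mu)^2)
  c(mean = mu, variance = v, skewness = mean((vals - mu)^3) / v^1.5)
}

# Inverse-CDF sampler for the GPD in the parameterisation
# F(y) = 1 - (1 - xi y / sigma)^(1/xi).
rgpd <- function(n, sigma, xi) {
  u <- runif(n)
  if (abs(xi) < 1e-12) -sigma * log(u) else sigma * (1 - u^xi) / xi
}
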