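# Independent oracles used across tests. These deliberately avoid the
# package's own likelihood code paths: the mixed-model oracle builds the full
# marginal covariance matrix and evaluates the Gaussian log-density via a
# Cholesky factorization.

# Log-likelihood of the random-intercept model at explicit variance
# components, with beta profiled by GLS on the full covariance matrix.
lmm_loglik_dense <- function(y, X, g, sigma_u2, sigma_e2, method = "ML") {
  Z <- stats::model.matrix(~ 0 + factor(g))
  V <- sigma_e2 * diag(length(y)) + sigma_u2 * tcrossprod(Z)
  ch <- chol(V)
  solve_V <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  ViX <- solve_V(X)
  Viy <- solve_V(y)
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(X, Viy))
  r <- as.numeric(y - X %*% beta)
  q <- sum(r * solve_V(r))
  logdet <- 2 * sum(log(diag(ch)))
  n <- length(y); p <- ncol(X)
  if (method == "ML") {
    -0.5 * (n * log(2 * pi) + logdet + q)
  } else {
    -0.5 * ((n - p) * log(2 * pi) + logdet + q +
              determinant(XtViX, logarithm = TRUE)$modulus)
  }
}

# Best log-likelihood over a 2-D variance-component grid (beta profiled).
lmm_grid_oracle <- function(y, X, g, method = "ML",
                            n_u = 35, n_e = 35) {
  vy <- stats::var(y)
  su2 <- c(0, exp(seq(log(vy * 1e-4), log(vy * 5), length.out = n_u - 1)))
  se2 <- exp(seq(log(vy * 2e-3), log(vy * 5), length.out = n_e))
  best <- -Inf
  for (a in su2) for (b in se2) {
    ll <- lmm_loglik_dense(y, X, g, a, b, method)
    if (ll > best) best <- ll
  }
  best
}

# Random small mixed-model instance for oracle-equivalence checks.
random_lmm_instance <- function(seed) {
  set.seed(seed)
  n_sites <- sample(2:6, 1)
  n_i <- sample(3:10, n_sites, replace = TRUE)
  g <- rep(seq_len(n_sites), n_i)
  x <- rnorm(sum(n_i), 10, 3)
  u <- rnorm(n_sites, 0, runif(1, 0, 1.5))
  y <- 2 + 0.4 * x + u[g] + rnorm(sum(n_i), 0, runif(1, 0.2, 1.5))
  list(y = y, x = x, g = g,
       records = data.frame(site_id = paste0("s", g), ctmax = y,
                            recovered = TRUE))
}

# Small deterministic hourly series for metric tests.
make_hourly <- function(values, start = "2021-06-01 00:00:00",
                        site = "toy", source = "recorded", tz = "UTC") {
  t0 <- as.POSIXct(start, tz = tz)
  temp_series(t0 + 3600 * (seq_along(values) - 1), values, source,
              site_id = site)
}

utc <- function(x) as.POSIXct(x, tz = "UTC")
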