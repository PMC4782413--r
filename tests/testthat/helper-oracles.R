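# Independent oracles: the statistics evaluated as literal double sums over
# sample pairs, kept deliberately naive and separate from the package's
# matrix-form implementation.

loop_nb_statistic <- function(y, mu, phi, R) {
  n <- length(y)
  u <- 0
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      u <- u + R[i, k] / 2 *
        (y[i] - mu[i]) * (y[k] - mu[k]) /
        ((1 + phi * mu[i]) * (1 + phi * mu[k]))
    }
  }
  for (i in seq_len(n)) {
    u <- u - R[i, i] / 2 * (mu[i] + y[i] * phi * mu[i]) / (1 + phi * mu[i])^2
  }
  u
}

loop_pois_statistic <- function(y, mu, R) {
  n <- length(y)
  u <- 0
  for (i in seq_len(n))
    for (k in seq_len(n))
      u <- u + R[i, k] / 2 * (y[i] - mu[i]) * (y[k] - mu[k])
  u - sum(diag(R) * mu) / 2
}

loop_sample_contributions <- function(y, mu, phi, R) {
  n <- length(y)
  s <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(n)) {
      acc <- acc + R[i, k] / 2 *
        (y[i] - mu[i]) * (y[k] - mu[k]) /
        ((1 + phi * mu[i]) * (1 + phi * mu[k]))
    }
    s[i] <- acc - R[i, i] / 2 * (mu[i] + y[i] * phi * mu[i]) /
      (1 + phi * mu[i])^2
  }
  s
}

loop_covariate_contributions <- function(y, mu, phi, X) {
  p <- ncol(X)
  n <- nrow(X)
  cc <- numeric(p)
  for (j in seq_len(p)) {
    lin <- 0
    quad <- 0
    for (i in seq_len(n)) {
      lin <- lin + X[i, j] * (y[i] - mu[i]) / (1 + phi * mu[i])
      quad <- quad + X[i, j]^2 / (2 * p) *
        (mu[i] + y[i] * phi * mu[i]) / (1 + phi * mu[i])^2
    }
    cc[j] <- lin^2 / (2 * p) - quad
  }
  cc
}

# A random small test instance with positive means and a PSD kernel.
random_instance <- function(n, p) {
  X <- matrix(stats::rnorm(n * p), n, p)
  list(
    y = stats::rpois(n, 5),
    mu = stats::runif(n, 0.5, 8),
    phi = stats::runif(1, 0, 2),
    X = X,
    R = tcrossprod(X) / p
  )
}

# Naive NB/Poisson maximum likelihood over (alpha, log phi) by generic
# optimisation; independent of the package's profile-Newton fit.
numeric_ml_fit <- function(y, multiplier, family = "negative_binomial") {
  negll_pois <- function(a) -nb_log_likelihood(y, multiplier * exp(a), 0)
  a0 <- stats::optimize(negll_pois, c(-20, 20), tol = 1e-10)$minimum
  if (family == "poisson") return(list(alpha = a0, phi = 0))
  negll <- function(par) -nb_log_likelihood(y, multiplier * exp(par[1]),
                                            exp(par[2]))
  best <- stats::optim(c(a0, 0), negll, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 5000))
  list(alpha = best$par[1], phi = exp(best$par[2]), loglik = -best$value)
}
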