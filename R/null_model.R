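#' Negative binomial log-likelihood
#'
#' Sum of log densities of independent NB observations in the
#' mean/dispersion parametrisation `E[y] = mu`, `Var[y] = mu + phi * mu^2`.
#' At `phi = 0` this is the Poisson log-likelihood, the continuous limit of
#' the NB family as the dispersion vanishes.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Vector of positive means, same length as `y`.
#' @param phi Dispersion parameter, a single number `>= 0`.
#' @return The log-likelihood, a single number.
#' @examples
#' nb_log_likelihood(0, 1, 0)   # log Poisson P(0) = -1
#' nb_log_likelihood(2, 2, 1)
#' @export
nb_log_likelihood <- function(y, mu, phi) {
  if (length(mu) != length(y)) stop_invalid("'y' and 'mu' lengths differ")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi < 0)
    stop_invalid("'phi' must be a single number >= 0")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop_invalid("'mu' must be positive")
  if (phi == 0) sum(stats::dpois(y, lambda = mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit the intercept-only null model
#'
#' Maximum-likelihood fit of the model with no covariate effects: all
#' samples share the intercept `alpha`, and the mean of sample `i` is
#' `mu_i = (m_i / m_bar) * exp(alpha)` (or simply `exp(alpha)` when
#' offsets are disabled). For the Poisson family the solution is closed
#' form, `exp(alpha_hat) = m_bar * sum(y) / sum(m)`. For the negative
#' binomial family the dispersion `phi` is profiled out: for each candidate
#' `phi` the intercept is found by Newton iteration on the stationarity
#' condition `sum((y - mu) / (1 + phi * mu)) = 0`, and the profile
#' log-likelihood is then maximised over `log(phi)` by bounded scalar
#' search, initialised at the method-of-moments value
#' `max(0, (s^2 - ybar) / ybar^2)`. A fit on the boundary is reported as
#' `phi_hat = 0`, where the NB statistic reduces exactly to the Poisson one.
#'
#' A response that is zero in every sample has no finite intercept; such
#' genes carry no information and raise a degenerate-response error
#' (condition class `"nbglobal_degenerate_response"`). Genome-wide drivers
#' skip them with a flag.
#'
#' @param resp A [count_response()] object (bare count vectors are
#'   promoted with offsets disabled).
#' @param family `"negative_binomial"` (default) or `"poisson"`.
#' @return An object of class `"null_fit"`: list with `family`,
#'   `alpha_hat`, `phi_hat`, `mu_hat`, `loglik`, `offset_enabled`.
#' @examples
#' fit_null(count_response(c(1, 2, 3)), family = "poisson")
#' fit_null(count_response(rpois(40, 6)))
#' @export
fit_null <- function(resp, family = c("negative_binomial", "poisson")) {
  family <- match.arg(family)
  if (!inherits(resp, "count_response")) resp <- count_response(resp)
  y <- resp$y
  tm <- resp$multiplier
  n <- length(y)
  if (n < 2L) stop_invalid("at least two samples are required")
  if (all(y == 0))
    stop_degenerate("all counts are zero: the intercept is -Inf and the test is undefined")

  alpha_pois <- log(sum(y) / sum(tm))

  if (family == "poisson") {
    mu <- tm * exp(alpha_pois)
    return(new_null_fit("poisson", alpha_pois, 0, mu,
                        nb_log_likelihood(y, mu, 0), resp$offset_enabled))
  }

  # profile the intercept for a fixed dispersion
  profile_alpha <- function(phi) {
    a <- alpha_pois
    for (iter in 1:100) {
      mu <- tm * exp(a)
      g <- sum((y - mu) / (1 + phi * mu))
      if (abs(g) < 1e-12 * max(1, sum(y))) break
      gprime <- -sum(mu * (1 + phi * y) / (1 + phi * mu)^2)
      step <- g / gprime
      # likelihood in alpha is well-behaved; damp absurd steps
      if (!is.finite(step)) break
      a <- a - max(min(step, 2), -2)
    }
    a
  }
  pll <- function(lphi) {
    phi <- exp(lphi)
    a <- profile_alpha(phi)
    nb_log_likelihood(y, tm * exp(a), phi)
  }

  ll0 <- nb_log_likelihood(y, tm * exp(alpha_pois), 0)
  ybar <- mean(y)
  phi_mom <- max(0, (stats::var(y) - ybar) / ybar^2)
  lo <- log(1e-8)
  hi <- log(max(1e3, 10 * max(phi_mom, 1)))
  opt <- stats::optimize(pll, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)

  if (opt$objective <= ll0 || exp(opt$maximum) < 1e-7) {
    # boundary: no evidence of overdispersion; NB collapses to Poisson
    phi_hat <- 0
    alpha_hat <- alpha_pois
    ll <- ll0
  } else {
    phi_hat <- exp(opt$maximum)
    alpha_hat <- profile_alpha(phi_hat)
    ll <- opt$objective
  }
  mu <- tm * exp(alpha_hat)
  new_null_fit("negative_binomial", alpha_hat, phi_hat, mu, ll,
               resp$offset_enabled)
}

new_null_fit <- function(family, alpha_hat, phi_hat, mu_hat, loglik,
                         offset_enabled) {
  structure(
    list(family = family, alpha_hat = alpha_hat, phi_hat = phi_hat,
         mu_hat = mu_hat, loglik = loglik, offset_enabled = offset_enabled),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, digits = 4, ...) {
  cat("Null model fit (", x$family, ")\n", sep = "")
  cat("  alpha_hat =", signif(x$alpha_hat, digits),
      " phi_hat =", signif(x$phi_hat, digits),
      " loglik =", signif(x$loglik, digits), "\n")
  invisible(x)
}

#' Serialize / restore a null fit
#'
#' Flat key-value representation used for caching fits across runs.
#'
#' @param fit A `"null_fit"` object.
#' @return `null_fit_record()` returns a named list of atomic fields;
#'   `null_fit_from_record()` reverses it.
#' @keywords internal
#' @export
null_fit_record <- function(fit) {
  list(family = fit$family, alpha_hat = fit$alpha_hat, phi_hat = fit$phi_hat,
       mu_hat = fit$mu_hat, loglik = fit$loglik,
       offset_enabled = fit$offset_enabled)
}

#' @rdname null_fit_record
#' @param record A list as produced by `null_fit_record()`.
#' @export
null_fit_from_record <- function(record) {
  new_null_fit(record$family, record$alpha_hat, record$phi_hat,
               record$mu_hat, record$loglik, record$offset_enabled)
}
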