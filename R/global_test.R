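#' Covariate set with its sample-similarity kernel
#'
#' Wraps an `n x p` covariate matrix (samples in rows). The global test
#' only sees the covariates through the `n x n` kernel
#' `R = (1/p) X X'`, which averages covariate similarity between samples
#' and is well-defined for any `p`, including `p >> n`. The kernel is
#' computed lazily and cached.
#'
#' Columns are used exactly as supplied; set `center = TRUE` to subtract
#' column means first (this changes `R` and therefore the test).
#'
#' @param X Numeric matrix, samples in rows, covariates in columns.
#' @param ids Covariate labels; defaults to column names or `V1..Vp`.
#' @param center Center columns before building the kernel? Default `FALSE`.
#' @return An object of class `"covariate_set"`.
#' @examples
#' cs <- covariate_set(matrix(rbinom(40, 2, 0.3), nrow = 10))
#' dim(covariance_kernel(cs))
#' @export
covariate_set <- function(X, ids = NULL, center = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) < 1L || nrow(X) < 1L)
    stop_invalid("'X' must have at least one row and one column")
  if (!is.numeric(X) || any(!is.finite(X)))
    stop_invalid("'X' must be a finite numeric matrix")
  if (isTRUE(center)) X <- sweep(X, 2L, colMeans(X))
  if (is.null(ids)) ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(X)))
  if (length(ids) != ncol(X)) stop_invalid("'ids' must label every column")
  structure(list(X = X, ids = as.character(ids),
                 cache = new.env(parent = emptyenv())),
            class = "covariate_set")
}

#' Kernel matrix of a covariate set
#'
#' @param x A `"covariate_set"` or a bare numeric matrix `X`.
#' @return The symmetric positive semi-definite matrix `(1/p) X X'`.
#' @export
covariance_kernel <- function(x) UseMethod("covariance_kernel")

#' @export
covariance_kernel.covariate_set <- function(x) {
  if (is.null(x$cache$R)) x$cache$R <- covariance_kernel(x$X)
  x$cache$R
}

#' @export
covariance_kernel.default <- function(x) {
  X <- as.matrix(x)
  if (ncol(X) < 1L || nrow(X) < 1L) stop_invalid("empty covariate matrix")
  tcrossprod(X) / ncol(X)
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("Covariate set:", nrow(x$X), "samples x", ncol(x$X), "covariates\n")
  invisible(x)
}

# Weighted residuals e and penalty weights w entering every statistic:
#   e_i = (y_i - mu_i) / (1 + phi * mu_i)
#   w_i = (mu_i + y_i * phi * mu_i) / (1 + phi * mu_i)^2
score_ingredients <- function(y, mu, phi) {
  denom <- 1 + phi * mu
  list(e = (y - mu) / denom, w = (mu + y * phi * mu) / denom^2)
}

check_stat_args <- function(y, mu, phi, R) {
  n <- length(y)
  if (length(mu) != n) stop_invalid("'y' and 'mu' lengths differ")
  if (!is.matrix(R) || nrow(R) != n || ncol(R) != n)
    stop_invalid("'R' must be an n x n matrix matching length(y)")
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0)
    stop_invalid("'phi' must be a single number >= 0")
  if (any(mu <= 0)) stop_invalid("'mu' must be positive")
  invisible(NULL)
}

#' Negative binomial global score statistic
#'
#' The score statistic for the variance component of random covariate
#' effects, evaluated at the null fit. In matrix form it is
#' `u = e' R e / 2 - sum(diag(R) * w) / 2` with the weighted residuals
#' `e_i = (y_i - mu_i) / (1 + phi mu_i)` and penalty weights
#' `w_i = (mu_i + y_i phi mu_i) / (1 + phi mu_i)^2`; this equals the
#' explicit double sum over sample pairs. Large values indicate
#' association between the response and the covariate set.
#'
#' @param y Counts. @param mu_hat Null means. @param phi_hat Null
#'   dispersion (`>= 0`). @param R Kernel matrix from
#'   [covariance_kernel()].
#' @return The statistic, a single number.
#' @examples
#' y <- c(0, 2); mu <- c(1, 1); R <- covariance_kernel(cbind(c(1, 1)))
#' nb_statistic(y, mu, 0, R) # -1
#' @export
nb_statistic <- function(y, mu_hat, phi_hat, R) {
  check_stat_args(y, mu_hat, phi_hat, R)
  si <- score_ingredients(y, mu_hat, phi_hat)
  0.5 * drop(crossprod(si$e, R %*% si$e)) - 0.5 * sum(diag(R) * si$w)
}

#' Poisson global score statistic
#'
#' The `phi = 0` special case of [nb_statistic()]:
#' `u = (y - mu)' R (y - mu) / 2 - sum(diag(R) * mu) / 2`.
#'
#' @inheritParams nb_statistic
#' @return The statistic, a single number.
#' @export
pois_statistic <- function(y, mu_hat, R) {
  nb_statistic(y, mu_hat, 0, R)
}

#' Per-sample contributions to the global statistic
#'
#' Splits the statistic across samples:
#' `s_i = e_i (R e)_i / 2 - R_ii w_i / 2`, so that `sum(s) = u`.
#' Positive contributions increase the evidence against the null; a
#' sample's contribution depends on the other samples through `R`,
#' `mu` and `phi`.
#'
#' @inheritParams nb_statistic
#' @return Numeric vector of length `n` summing to the statistic.
#' @export
sample_contributions <- function(y, mu_hat, phi_hat, R) {
  check_stat_args(y, mu_hat, phi_hat, R)
  si <- score_ingredients(y, mu_hat, phi_hat)
  0.5 * si$e * drop(R %*% si$e) - 0.5 * diag(R) * si$w
}

#' Per-covariate contributions to the global statistic
#'
#' Splits the statistic across covariates:
#' `c_j = ((x_j' e)^2 - sum(x_j^2 * w)) / (2 p)`, so that `sum(c) = u`.
#' Each `c_j` depends only on covariate `j`; multiplying `c_j` by `p`
#' gives exactly the statistic that testing covariate `j` alone would
#' produce.
#'
#' @inheritParams nb_statistic
#' @param X The `n x p` covariate matrix itself (not the kernel).
#' @return Numeric vector of length `p` summing to the statistic.
#' @export
covariate_contributions <- function(y, mu_hat, phi_hat, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_invalid("'X' rows must match length(y)")
  if (any(mu_hat <= 0)) stop_invalid("'mu_hat' must be positive")
  if (!is.numeric(phi_hat) || length(phi_hat) != 1L || phi_hat < 0)
    stop_invalid("'phi_hat' must be a single number >= 0")
  si <- score_ingredients(y, mu_hat, phi_hat)
  p <- ncol(X)
  a <- drop(crossprod(X, si$e))
  (a^2 - drop(crossprod(X^2, si$w))) / (2 * p)
}

#' Statistic for a group of covariates
#'
#' The statistic for a covariate group is the average of the
#' single-covariate statistics, i.e. the statistic obtained by testing
#' only the group's columns.
#'
#' @inheritParams covariate_contributions
#' @param group Column indices (or covariate ids when `X` has column
#'   names) defining the group.
#' @return The group statistic, a single number.
#' @export
group_statistic <- function(y, mu_hat, phi_hat, X, group) {
  X <- as.matrix(X)
  if (is.character(group)) {
    group <- match(group, colnames(X))
    if (anyNA(group)) stop_invalid("unknown covariate ids in 'group'")
  }
  if (length(group) < 1L || any(group < 1L) || any(group > ncol(X)))
    stop_invalid("'group' must index columns of 'X'")
  cc <- covariate_contributions(y, mu_hat, phi_hat, X)
  ncol(X) * mean(cc[group])
}
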