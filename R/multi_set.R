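#' Permutation moments of a statistic
#'
#' Sample mean and (denominator `k`) variance of the permuted statistics
#' of one covariate set; used to standardise per-set statistics before
#' summing them in the joint test.
#'
#' @param perm_stats Numeric vector of `k >= 2` permutation statistics
#'   (observed draw included).
#' @return List with `mean` and `variance`.
#' @export
estimate_moments <- function(perm_stats) {
  k <- length(perm_stats)
  if (k < 2L) stop_invalid("at least two permutation statistics are required")
  m <- mean(perm_stats)
  v <- mean((perm_stats - m)^2)
  if (v <= 0)
    stop_degenerate_set("permutation statistics are constant: the set carries no permutation signal")
  list(mean = m, variance = v)
}

#' Standardised-sum joint statistic
#'
#' Centres and scales each covariate set's statistic by its estimated
#' permutation moments and sums the resulting z-scores. With any number
#' of sets the joint statistic is the standardised sum of the individual
#' statistics; no cross-set covariance term is used (ignoring that
#' correlation costs little power).
#'
#' @param u Numeric vector of per-set statistics.
#' @param moments List of per-set moment lists, each with `mean` and
#'   `variance` (as from [estimate_moments()]).
#' @return The joint statistic, a single number.
#' @export
joint_statistic <- function(u, moments) {
  if (length(u) != length(moments))
    stop_invalid("'u' and 'moments' lengths differ")
  means <- vapply(moments, `[[`, numeric(1), "mean")
  vars <- vapply(moments, `[[`, numeric(1), "variance")
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop_invalid("every permutation variance must be positive and finite")
  sum((u - means) / sqrt(vars))
}

#' Joint test of multiple covariate sets
#'
#' Tests several molecular profiles (e.g. copy number and methylation)
#' against one count response simultaneously. A single null fit and a
#' single shared permutation stream drive all sets: each permutation
#' yields one statistic per set, per-set moments are estimated from
#' those statistics (observed draw included), and the joint statistic of
#' every permutation is standardised with the same global moment
#' estimates, so a one-set joint test reproduces the crude per-set
#' p-value exactly.
#'
#' @inheritParams run_test
#' @param sets A list of [covariate_set()] objects (or matrices) sharing
#'   the sample order of `resp`.
#' @return An object of class `"joint_test_result"`: `per_set` (a
#'   data.frame with id, u_obs, permutation mean/variance, z and the
#'   individual p-value), `u_joint_obs`, `u_joint_perm`, `p_joint`, `k`,
#'   `seed`, `family`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20); Z <- matrix(rnorm(40), 20)
#' y <- rpois(20, 4)
#' run_joint_test(y, list(snp = X, meth = Z), k = 100, seed = 3)
#' @export
run_joint_test <- function(resp, sets,
                           family = c("negative_binomial", "poisson"),
                           k = 1000, strata = NULL, seed = NULL) {
  family <- match.arg(family)
  if (!inherits(resp, "count_response")) resp <- count_response(resp)
  if (!is.list(sets) || length(sets) < 1L)
    stop_invalid("'sets' must be a non-empty list of covariate sets")
  set_ids <- names(sets)
  if (is.null(set_ids)) set_ids <- paste0("set", seq_along(sets))
  sets <- lapply(sets, function(s)
    if (inherits(s, "covariate_set")) s else covariate_set(s))
  y <- resp$y
  n <- length(y)
  for (s in sets)
    if (nrow(s$X) != n) stop_invalid("every set must share the sample order of 'resp'")
  k <- as.integer(k)
  if (k < 2L) stop_invalid("'k' must be at least 2 for moment estimation")

  fit <- fit_null(resp, family = family)
  si <- score_ingredients(y, fit$mu_hat, fit$phi_hat)
  kernels <- lapply(sets, covariance_kernel)
  dRs <- lapply(kernels, diag)
  nset <- length(sets)

  stats_mat <- matrix(NA_real_, k, nset,
                      dimnames = list(NULL, set_ids))
  stats_mat[1L, ] <- vapply(seq_len(nset), function(j) {
    0.5 * drop(crossprod(si$e, kernels[[j]] %*% si$e)) -
      0.5 * sum(dRs[[j]] * si$w)
  }, numeric(1))

  blocks <- split_strata(n, strata)
  with_seed(seed, {
    for (i in seq_len(k - 1L)) {
      perm <- seq_len(n)
      for (block in blocks)
        if (length(block) > 1L) perm[block] <- block[sample.int(length(block))]
      ep <- si$e[perm]
      wp <- si$w[perm]
      stats_mat[i + 1L, ] <- vapply(seq_len(nset), function(j) {
        0.5 * drop(crossprod(ep, kernels[[j]] %*% ep)) -
          0.5 * sum(dRs[[j]] * wp)
      }, numeric(1))
    }
  })

  moments <- lapply(seq_len(nset), function(j) estimate_moments(stats_mat[, j]))
  means <- vapply(moments, `[[`, numeric(1), "mean")
  sds <- sqrt(vapply(moments, `[[`, numeric(1), "variance"))
  zmat <- sweep(sweep(stats_mat, 2L, means), 2L, sds, "/")
  joint_perm <- rowSums(zmat)
  p_joint <- permutation_pvalue(joint_perm[1L], joint_perm)
  per_set_p <- vapply(seq_len(nset), function(j)
    permutation_pvalue(stats_mat[1L, j], stats_mat[, j]), numeric(1))

  per_set <- data.frame(
    id = set_ids,
    u_obs = stats_mat[1L, ],
    perm_mean = means,
    perm_var = sds^2,
    z = zmat[1L, ],
    p_value = per_set_p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(per_set = per_set, u_joint_obs = joint_perm[1L],
         u_joint_perm = joint_perm, p_joint = p_joint,
         perm_stats = stats_mat, k = k, seed = seed, family = fit$family,
         fit = fit),
    class = "joint_test_result"
  )
}

#' @export
print.joint_test_result <- function(x, digits = 4, ...) {
  cat("Joint global test over", nrow(x$per_set), "covariate sets\n")
  cat("  joint u =", signif(x$u_joint_obs, digits),
      " p_joint =", signif(x$p_joint, digits),
      " (k =", x$k, "draws)\n")
  print(cbind(x$per_set[, c("id", "u_obs", "z")],
              p = signif(x$per_set$p_value, digits)), row.names = FALSE)
  invisible(x)
}
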