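#' Configuration for the simulation studies
#'
#' Collects the knobs of the synthetic-data protocol: covariates are
#' correlated SNP-dosage blocks (emulating local linkage disequilibrium),
#' a consecutive run of `r` coefficients is given the value `s` with
#' probability 0.8 and `2s` with probability 0.2, the mean vector is
#' `mu = X beta` on the identity scale, and responses are drawn from
#' `NB(mu_i, phi)` (`phi = 0` draws Poisson). Data under the null are
#' produced by shuffling the elements of `mu` before sampling, which
#' preserves the marginal count distribution while breaking the
#' association with `X`.
#'
#' @param n Samples. @param p Covariates. @param r Length of the
#'   non-zero coefficient run. @param s Effect size (> 0). @param phi
#'   Dispersion (>= 0). @param n_alt,n_null Replicates per arm.
#' @param k Permutations per test. @param seed Master seed.
#' @param block_size,rho,maf_range Genotype-block parameters: columns per
#'   linkage block, latent within-block correlation, and the range minor
#'   allele frequencies are drawn from.
#' @param family Model family used by the test.
#' @param alphas Significance levels at which rejection rates are
#'   reported.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 50, p = 20, r = 5, s = 1, phi = 0.5,
                              n_alt = 200, n_null = 200, k = 200,
                              seed = 1L, block_size = 10, rho = 0.5,
                              maf_range = c(0.1, 0.4),
                              family = "negative_binomial",
                              alphas = c(0.01, 0.05, 0.1)) {
  if (r < 1 || r > p) stop_invalid("'r' must satisfy 1 <= r <= p")
  if (s <= 0) stop_invalid("'s' must be positive")
  if (phi < 0) stop_invalid("'phi' must be >= 0")
  if (n_alt < 1 || n_null < 1) stop_invalid("replicate counts must be >= 1")
  structure(list(n = n, p = p, r = r, s = s, phi = phi, n_alt = n_alt,
                 n_null = n_null, k = k, seed = seed,
                 block_size = block_size, rho = rho, maf_range = maf_range,
                 family = family, alphas = alphas),
            class = "simulation_config")
}

#' Synthetic SNP dosages with local correlation
#'
#' Draws an `n x p` matrix of minor-allele dosages (0, 1 or 2). Latent
#' standard normal variables are equicorrelated within consecutive
#' blocks of `block_size` columns (correlation `rho`) and independent
#' across blocks, then thresholded at the Hardy-Weinberg quantiles of a
#' per-column minor allele frequency drawn uniformly from `maf_range`.
#' Adjacent columns within a block are therefore positively correlated,
#' mimicking linkage disequilibrium between neighbouring SNPs.
#'
#' Uses the ambient RNG stream; call [set.seed()] (or wrap in a seeded
#' study) for reproducibility.
#'
#' @param n Samples. @param p Columns (SNPs).
#' @param block_size Columns per linkage block.
#' @param rho Latent within-block correlation, in `[0, 1)`.
#' @param maf_range Interval in `(0, 0.5]` for minor allele frequencies.
#' @return Integer-valued `n x p` matrix of dosages.
#' @examples
#' set.seed(1)
#' X <- synthetic_genotypes(100, 20)
#' @export
synthetic_genotypes <- function(n, p, block_size = 10, rho = 0.5,
                                maf_range = c(0.1, 0.4)) {
  if (rho < 0 || rho >= 1) stop_invalid("'rho' must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_invalid("'maf_range' must be an interval within (0, 0.5]")
  block <- rep(seq_len(ceiling(p / block_size)), each = block_size)[seq_len(p)]
  shared <- matrix(stats::rnorm(n * max(block)), n)
  latent <- sqrt(rho) * shared[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * p), n)
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  # HWE genotype probabilities: (1-f)^2, 2f(1-f), f^2
  q0 <- stats::qnorm((1 - maf)^2)
  q1 <- stats::qnorm(1 - maf^2)
  dosage <- (latent > rep(q0, each = n)) + (latent > rep(q1, each = n))
  storage.mode(dosage) <- "double"
  dosage
}

#' Draw a sparse coefficient vector
#'
#' All coefficients start at zero; a uniformly placed run of `r`
#' consecutive coefficients is then assigned the value `s` with
#' probability 0.8 and `2s` with probability 0.2, independently.
#'
#' @param p Number of coefficients. @param r Run length (`<= p`).
#' @param s Effect size.
#' @return List of class `"coefficient_vector"` with `beta` (length `p`)
#'   and `run_start`.
#' @export
draw_coefficients <- function(p, r, s) {
  if (r > p) stop_invalid("'r' must not exceed 'p'")
  if (r < 1) stop_invalid("'r' must be >= 1")
  beta <- numeric(p)
  start <- sample.int(p - r + 1L, 1L)
  beta[start:(start + r - 1L)] <- sample(c(s, 2 * s), r, replace = TRUE,
                                         prob = c(0.8, 0.2))
  structure(list(beta = beta, run_start = start),
            class = "coefficient_vector")
}

#' Simulate a count response from the generator model
#'
#' Computes `mu = X beta` on the identity scale (the generator's link,
#' deliberately different from the log link the test uses), optionally
#' shuffles `mu` to produce data under the null with the same marginal
#' count distribution, and samples `y_i ~ NB(mu_i, phi)`; `phi = 0`
#' samples Poisson, and `mu_i = 0` yields `y_i = 0` with probability
#' one.
#'
#' @param X Covariate matrix (non-negative when `beta` is non-negative).
#' @param beta Coefficient vector or a [draw_coefficients()] result.
#' @param phi Dispersion (`>= 0`).
#' @param null_shuffle Shuffle `mu` before sampling?
#' @param baseline Optional additive constant on `mu` (default 0).
#' @return Integer count vector of length `nrow(X)`.
#' @export
simulate_response <- function(X, beta, phi, null_shuffle = FALSE,
                              baseline = 0) {
  if (inherits(beta, "coefficient_vector")) beta <- beta$beta
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop_invalid("'beta' must match ncol(X)")
  if (phi < 0) stop_invalid("'phi' must be >= 0")
  mu <- drop(X %*% beta) + baseline
  if (any(mu < 0))
    stop_invalid("negative mean: the generator requires mu = X beta >= 0")
  if (isTRUE(null_shuffle)) mu <- sample(mu)
  if (phi == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
}

# Rank (Mann-Whitney) AUC: probability that an alternative-arm p-value is
# smaller than a null-arm p-value, ties counted half.
rank_auc <- function(p_alt, p_null) {
  na <- length(p_alt); nn <- length(p_null)
  r <- rank(c(p_alt, p_null))
  u_alt_greater <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  1 - u_alt_greater / (na * nn)
}

run_one_sim_test <- function(y, X, config) {
  res <- tryCatch(
    run_test(y, X, family = config$family, k = config$k, seed = NULL),
    nbglobal_degenerate_response = function(cnd) NULL
  )
  if (is.null(res)) NA_real_ else res$p_value
}

#' Power and type-I error study
#'
#' Runs the simulation protocol over one or more conditions. For each
#' condition, one covariate matrix is generated and held fixed,
#' `n_alt` responses are simulated under the alternative and `n_null`
#' responses under the shuffled-mean null, each replicate is tested, and
#' the condition is summarised by the rank-based AUC of the ROC curve
#' (alternative vs null p-values) plus rejection rates in both arms at
#' the configured significance levels. Degenerate replicates (all-zero
#' responses) are dropped with a count.
#'
#' When varying the run length `r`, the coefficient subset is not
#' redrawn per level: each replicate draws the run at the largest level
#' and shorter levels truncate it in place.
#'
#' @param config A [simulation_config()].
#' @param vary Optional factor to vary: one of `"s"`, `"n"`, `"phi"`,
#'   `"r"`; `NULL` runs the single configured condition.
#' @param levels Values of the varied factor.
#' @return A data.frame, one row per condition: `factor`, `level`,
#'   `auc`, `power_<alpha>` and `typeI_<alpha>` columns, and dropped
#'   replicate counts. Reproducible from `config$seed`.
#' @export
power_study <- function(config, vary = NULL, levels = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(vary)) {
    vary <- "s"
    levels <- config$s
  }
  vary <- match.arg(vary, c("s", "n", "phi", "r"))
  if (is.null(levels)) stop_invalid("'levels' must be given when 'vary' is set")

  with_seed(config$seed, {
    rows <- lapply(levels, function(lev) {
      cfg <- config
      cfg[[vary]] <- lev
      X <- synthetic_genotypes(cfg$n, cfg$p, cfg$block_size, cfg$rho,
                               cfg$maf_range)
      r_draw <- if (vary == "r") max(levels) else cfg$r
      p_alt <- rep(NA_real_, cfg$n_alt)
      p_null <- rep(NA_real_, cfg$n_null)
      for (i in seq_len(cfg$n_alt)) {
        coef <- draw_coefficients(cfg$p, r_draw, cfg$s)
        beta <- truncate_run(coef, cfg$r)
        y <- simulate_response(X, beta, cfg$phi)
        p_alt[i] <- run_one_sim_test(y, X, cfg)
      }
      for (i in seq_len(cfg$n_null)) {
        coef <- draw_coefficients(cfg$p, r_draw, cfg$s)
        beta <- truncate_run(coef, cfg$r)
        y <- simulate_response(X, beta, cfg$phi, null_shuffle = TRUE)
        p_null[i] <- run_one_sim_test(y, X, cfg)
      }
      dropped <- sum(is.na(p_alt)) + sum(is.na(p_null))
      p_alt <- p_alt[!is.na(p_alt)]
      p_null <- p_null[!is.na(p_null)]
      out <- data.frame(factor = vary, level = lev,
                        auc = rank_auc(p_alt, p_null),
                        dropped = dropped)
      for (a in config$alphas) {
        out[[paste0("power_", a)]] <- mean(p_alt <= a)
        out[[paste0("typeI_", a)]] <- mean(p_null <= a)
      }
      out
    })
    do.call(rbind, rows)
  })
}

truncate_run <- function(coef, r) {
  beta <- coef$beta
  run <- which(beta != 0)
  if (length(run) > r) beta[run[-seq_len(r)]] <- 0
  beta
}

#' Joint versus individual covariate testing
#'
#' Compares, replicate by replicate, the p-value of testing all `p`
#' covariates at once against the minimum of the `p`
#' Benjamini-Hochberg-adjusted single-covariate p-values. Each replicate
#' draws a fresh covariate matrix, gives *every* coefficient a non-zero
#' value (the many-small-effects regime), simulates one response, and
#' evaluates both approaches on the same permutation stream: the
#' single-covariate statistics are obtained from the per-covariate
#' decomposition of each permuted configuration, so no extra
#' permutations are needed. A null arm with shuffled means checks
#' calibration of both approaches.
#'
#' @param config A [simulation_config()]; `r` is ignored (all
#'   coefficients are non-zero here).
#' @return A data.frame with one row per replicate: `replicate`, `arm`
#'   (`"alt"` or `"null"`), `p_joint`, `min_fdr_p`.
#' @export
joint_vs_individual_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    one_arm <- function(arm, n_rep) {
      rows <- vector("list", n_rep)
      for (i in seq_len(n_rep)) {
        X <- synthetic_genotypes(config$n, config$p, config$block_size,
                                 config$rho, config$maf_range)
        beta <- sample(c(config$s, 2 * config$s), config$p, replace = TRUE,
                       prob = c(0.8, 0.2))
        y <- simulate_response(X, beta, config$phi,
                               null_shuffle = (arm == "null"))
        pv <- joint_and_individual_pvalues(y, X, config)
        rows[[i]] <- data.frame(replicate = i, arm = arm,
                                p_joint = pv$p_joint,
                                min_fdr_p = pv$min_fdr_p)
      }
      do.call(rbind, rows)
    }
    rbind(one_arm("alt", config$n_alt), one_arm("null", config$n_null))
  })
}

# Joint p-value and minimum BH-adjusted individual p-value from one shared
# permutation stream. Individual statistics are p * c_j, recomputed for
# each permuted configuration from the covariate decomposition.
joint_and_individual_pvalues <- function(y, X, config) {
  resp <- count_response(y)
  fit <- tryCatch(fit_null(resp, family = config$family),
                  nbglobal_degenerate_response = function(cnd) NULL)
  if (is.null(fit)) return(list(p_joint = NA_real_, min_fdr_p = NA_real_))
  si <- score_ingredients(y, fit$mu_hat, fit$phi_hat)
  R <- covariance_kernel(X)
  dR <- diag(R)
  p <- ncol(X)
  X2 <- X^2
  k <- config$k

  stat_all <- function(e, w) {
    a <- drop(crossprod(X, e))
    indiv <- (a^2 - drop(crossprod(X2, w))) / 2   # = p * c_j
    u <- sum(indiv) / p
    c(u, indiv)
  }
  n <- length(y)
  mat <- matrix(NA_real_, k, p + 1L)
  mat[1L, ] <- stat_all(si$e, si$w)
  for (i in seq_len(k - 1L)) {
    perm <- sample.int(n)
    mat[i + 1L, ] <- stat_all(si$e[perm], si$w[perm])
  }
  pvals <- vapply(seq_len(p + 1L), function(j)
    mean(mat[, j] >= mat[1L, j]), numeric(1))
  list(p_joint = pvals[1L],
       min_fdr_p = min(stats::p.adjust(pvals[-1L], method = "BH")))
}
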