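# Internal helpers: typed conditions, seeded evaluation, permutations.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nbglobal_invalid_input", "error", "condition")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("nbglobal_degenerate_response",
                                     "nbglobal_invalid_input",
                                     "error", "condition")))
}

stop_degenerate_set <- function(msg) {
  stop(errorCondition(msg, class = c("nbglobal_degenerate_set",
                                     "nbglobal_invalid_input",
                                     "error", "condition")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream. seed = NULL consumes the ambient stream instead (useful inside
# larger seeded simulations).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit seed from a master seed and a character id, so that
# per-gene permutation streams do not depend on gene order in the input.
derive_seed <- function(master_seed, id) {
  h <- 0
  for (code in utf8ToInt(as.character(id))) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (as.numeric(master_seed) %% 2147483647) * 7919) %% 2147483646 + 1)
}

# All n! permutations of 1..n as a matrix (rows). Only sensible for small n;
# used for exact permutation nulls and enumeration-based checks.
all_permutations <- function(n) {
  if (n > 8) stop_invalid("exhaustive enumeration supported only for n <= 8")
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(rep.int(i, nrow(sub)), sub + (sub >= i))
  }))
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
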