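#' Bundle a count response with its library sizes
#'
#' Represents the expression of one gene across `n` samples, together with
#' optional sequencing library sizes. When offsets are enabled, the model
#' mean for sample `i` is `mu_i = (m_i / m_bar) * exp(alpha)`, where `m_bar`
#' is the *geometric* mean of the library sizes, so the offset multipliers
#' `m_i / m_bar` have product one and the intercept keeps its interpretation
#' as a typical expression level.
#'
#' @param y Vector of non-negative integer counts, one per sample.
#' @param lib_sizes Optional vector of positive library sizes, same length
#'   as `y`. Defaults to all ones.
#' @param offset Logical; include the library-size offset `log(m_i / m_bar)`
#'   in the null model? Defaults to `TRUE` exactly when `lib_sizes` is
#'   supplied. Data already adjusted for sequencing depth should be used
#'   with `offset = FALSE`.
#'
#' @return An object of class `"count_response"`: a list with elements
#'   `y`, `lib_sizes`, `offset_enabled` and `multiplier` (the vector
#'   `exp(offset)`, all ones when offsets are disabled).
#'
#' @examples
#' count_response(c(3, 0, 7), lib_sizes = c(1e6, 2e6, 1.5e6))
#' @seealso [compute_offsets()], [fit_null()]
#' @export
count_response <- function(y, lib_sizes = NULL, offset = !is.null(lib_sizes)) {
  if (length(y) < 1L) stop_invalid("'y' must be non-empty")
  if (!is_whole(y) || any(y < 0))
    stop_invalid("'y' must contain non-negative integer counts")
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n)
  if (length(lib_sizes) != n)
    stop_invalid("'lib_sizes' must have the same length as 'y'")
  if (!is.numeric(lib_sizes) || any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop_invalid("library sizes must be positive and finite")
  multiplier <- if (isTRUE(offset)) exp(compute_offsets(lib_sizes)) else rep(1, n)
  structure(
    list(y = y, lib_sizes = as.numeric(lib_sizes),
         offset_enabled = isTRUE(offset), multiplier = multiplier),
    class = "count_response"
  )
}

#' Library-size offsets on the log scale
#'
#' Computes `log(m_i / m_bar)` with `m_bar` the geometric mean of the
#' library sizes `m`. The offsets sum to zero by construction, so the
#' exponentiated multipliers have geometric mean one.
#'
#' @param m Vector of positive library sizes.
#' @return Numeric vector of offsets, summing to zero.
#' @examples
#' compute_offsets(c(1, 4)) # -log(2), +log(2)
#' @export
compute_offsets <- function(m) {
  if (length(m) < 1L || !is.numeric(m) || any(!is.finite(m)) || any(m <= 0))
    stop_invalid("library sizes must be positive and finite")
  lm <- log(m)
  lm - mean(lm)
}

#' @export
print.count_response <- function(x, ...) {
  cat("Count response: n =", length(x$y),
      "| total =", sum(x$y),
      "| offsets", if (x$offset_enabled) "enabled" else "disabled", "\n")
  invisible(x)
}
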