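#' Bonferroni-style p-value adjustment with a testable-pattern count
#'
#' Multiplies a raw log-rank p-value by the correction factor `k` (the
#' number of testable combinations) and caps the result at 1. This is the
#' adjustment applied to every reported combination; significance itself is
#' decided by comparing the raw p-value against `alpha / k`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param k Positive correction factor (number of testable combinations).
#' @return Numeric vector of adjusted p-values, capped at 1.
#' @examples
#' adjust_pvalue(1e-6, 1000)
#' @export
adjust_pvalue <- function(p, k) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("`k` must be a single correction factor >= 1.")
  }
  pmin(1, p * k)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Deterministic collation for marker ids and result ordering: plain C-locale
# byte order, so output files do not depend on the session locale.
c_sort <- function(x) {
  x[order(x, method = "radix")]
}

c_order <- function(...) {
  order(..., method = "radix")
}
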