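#' Per-failure-time factor of the minimum p-value bound
#'
#' At the `j`-th failure time, the most biased 2x2 table a combination
#' with `lambda` carriers at risk could produce has Fisher hypergeometric
#' probability at least `choose(n_j, lambda) / choose(Y_j, lambda)` when
#' `lambda <= n_j` (all carriers fail), and at least `1 / choose(Y_j, n_j)`
#' otherwise (all `n_j` failures fall among the carriers; constant in
#' `lambda`, as required for monotonicity). Factors are evaluated through
#' log-gamma and are always in `(0, 1]`.
#'
#' @param lambda Positive integer support (carriers at risk).
#' @param j Failure-time index, `1 <= j <= nrow(risk)`.
#' @param risk A [build_risk_structure()] result.
#' @return The factor as a probability in `(0, 1]`.
#' @export
bound_factor <- function(lambda, j, risk) {
  check_risk(risk)
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > nrow(risk)) {
    abort(sprintf("failure-time index `j` must be in 1..%d.", nrow(risk)))
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 1) {
    abort("`lambda` must be a positive integer.")
  }
  exp(log_bound_factors(lambda, risk$at_risk, risk$failures)[j])
}

# vectorized log f_j(lambda) over all failure times for a single lambda
log_bound_factors <- function(lambda, Y, n) {
  ifelse(lambda <= n,
         lchoose(n, lambda) - lchoose(Y, lambda),
         -lchoose(Y, n))
}

#' Lower bound on the minimum attainable log-rank p-value
#'
#' For a combination carried by `lambda` samples, no log-rank p-value can
#' fall below `f(lambda)`, the product over all distinct failure times of
#' the per-table most-biased Fisher probabilities ([bound_factor()]).
#' `f` is monotone non-increasing in `lambda`, which is what lets the
#' support-threshold search prune infrequent combinations: if
#' `f(lambda) > alpha / k`, no combination with support `<= lambda` can
#' ever be significant. The product is accumulated in log space (with
#' hundreds of failure times it underflows double precision otherwise)
#' and `lambda` values beyond the largest risk-set size are clamped there,
#' where the bound is constant.
#'
#' @param lambda Vector of positive integer supports.
#' @param risk A [build_risk_structure()] result.
#' @return Numeric vector of bounds in `(0, 1]`, one per `lambda`.
#' @examples
#' clin <- tibble::tibble(sample_id = letters[1:4],
#'                        time = c(1, 2, 3, 4), event = c(1L, 0L, 0L, 0L))
#' min_pvalue_bound(1, build_risk_structure(clin))  # 1/4
#' @export
min_pvalue_bound <- function(lambda, risk) {
  check_risk(risk)
  if (!is.numeric(lambda) || any(lambda < 1)) {
    abort("`lambda` must be positive integer support value(s).")
  }
  lam_max <- max(risk$at_risk)
  vapply(pmin(lambda, lam_max), function(l) {
    exp(sum(log_bound_factors(l, risk$at_risk, risk$failures)))
  }, numeric(1))
}
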