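# Closed frequent itemset mining over the carrier matrix.
#
# Depth-first prefix-preserving closure extension (the traversal behind
# LCM): each closed pattern is generated exactly once, from the extension
# of its smallest non-prefix item, so no global duplicate table is needed.
# Carrier sets are kept as integer sample-index vectors; the closure of a
# carrier set T is every marker whose carriers include all of T.

mine_closed <- function(G, min_support) {
  M <- nrow(G)
  N <- ncol(G)
  acc <- new.env(parent = emptyenv())
  acc$markers <- vector("list", 64L)
  acc$tids <- vector("list", 64L)
  acc$n <- 0L

  emit <- function(items, tidx) {
    n <- acc$n + 1L
    if (n > length(acc$markers)) {
      length(acc$markers) <- 2L * length(acc$markers)
      length(acc$tids) <- 2L * length(acc$tids)
    }
    acc$markers[[n]] <- items
    acc$tids[[n]] <- tidx
    acc$n <- n
  }

  closure_of <- function(tidx) {
    which(rowSums(G[, tidx, drop = FALSE]) == length(tidx))
  }

  dfs <- function(tidx, closed, core) {
    cand <- which(!(seq_len(M) %in% closed))
    cand <- cand[cand > core]
    for (i in cand) {
      new_tidx <- tidx[G[i, tidx]]
      if (length(new_tidx) < min_support) next
      new_closed <- closure_of(new_tidx)
      below <- new_closed[new_closed < i]
      if (!all(below %in% closed)) next  # not prefix-preserving: generated elsewhere
      emit(new_closed, new_tidx)
      dfs(new_tidx, new_closed, i)
    }
  }

  root_tidx <- seq_len(N)
  root_closed <- closure_of(root_tidx)
  if (length(root_closed) > 0L && N >= min_support) {
    emit(root_closed, root_tidx)
  }
  dfs(root_tidx, root_closed, 0L)
  list(markers = acc$markers[seq_len(acc$n)], tids = acc$tids[seq_len(acc$n)])
}

#' Closed frequent marker combinations
#'
#' Enumerates every closed combination with support at least `min_support`.
#' A combination is closed when no additional marker can be added without
#' shrinking its carrier set; every frequent non-closed combination shares
#' its carrier set — and therefore its contingency tables and log-rank
#' p-value — with exactly one closed representative, so testing closed
#' combinations tests all combinations.
#'
#' @param ds A `survlamp_dataset`.
#' @param min_support Minimum support (positive integer).
#' @return A tibble sorted by support descending then combination label,
#'   with columns `markers` (list of sorted marker-id vectors), `pattern`
#'   (comma-joined label), `support`, and `carriers` (list of sample index
#'   vectors).
#' @examples
#' markers <- tibble::tibble(marker_id = c("A", "B"),
#'                           s1 = c(1, 1), s2 = c(1, 1), s3 = c(0, 0))
#' clin <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                        time = 1:3, event = c(1L, 1L, 1L))
#' closed_frequent_patterns(align_dataset(markers, clin), 2)
#' @export
closed_frequent_patterns <- function(ds, min_support) {
  check_dataset(ds)
  if (!is.numeric(min_support) || length(min_support) != 1L || min_support < 1) {
    abort("`min_support` must be a positive integer.")
  }
  res <- mine_closed(ds$markers, as.integer(min_support))
  ids <- purrr::map(res$markers, function(i) c_sort(ds$marker_ids[i]))
  out <- tibble(
    markers = ids,
    pattern = vapply(ids, paste, character(1), collapse = ","),
    support = vapply(res$tids, length, integer(1)),
    carriers = res$tids
  )
  out[c_order(-out$support, out$pattern), ]
}

#' LAMP support-threshold search for the log-rank test
#'
#' Finds the optimal support threshold `lambda*` balancing the number of
#' testable combinations against the minimum p-value they could attain.
#' `lambda` starts at the largest single-marker support (by
#' anti-monotonicity, the largest support of any combination), clamped to
#' the largest risk-set size (beyond which the bound is constant). At each
#' step the closed combinations with support `>= lambda` are enumerated
#' and counted (`k`); while `lambda > 2` and the bound at `lambda - 1`
#' satisfies `f(lambda - 1) <= alpha / k`, the threshold is lowered and the
#' mining repeated. On return, any combination with support below
#' `lambda*` has minimum attainable p-value above `alpha / k`, so it can
#' never be significant and does not inflate the correction factor.
#'
#' @param ds A `survlamp_dataset`.
#' @param alpha Target family-wise error rate in (0, 1), default 0.05.
#' @param risk Optional precomputed [build_risk_structure()] result.
#' @return A `lamp_outcome`: list with `lambda_star`, `k` (number of
#'   testable combinations), `alpha`, `delta` (= `alpha / k`), and
#'   `testable` (the [closed_frequent_patterns()] tibble at `lambda*`).
#'   Errors with class `survlamp_untestable` when no marker reaches
#'   support 2.
#' @seealso [enumerate_significant()], [min_pvalue_bound()]
#' @export
lamp_lambda_search <- function(ds, alpha = 0.05, risk = NULL) {
  check_dataset(ds)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  risk <- risk %||% build_risk_structure(ds)
  check_risk(risk)
  max_support <- max(rowSums(ds$markers))
  if (max_support < 2) {
    abort("no marker has support >= 2: nothing is testable.",
          class = "survlamp_untestable")
  }
  lambda <- max(2L, min(as.integer(max_support), max(risk$at_risk)))
  repeat {
    testable <- closed_frequent_patterns(ds, lambda)
    k <- nrow(testable)
    if (lambda > 2L && min_pvalue_bound(lambda - 1L, risk) <= alpha / k) {
      lambda <- lambda - 1L
    } else {
      break
    }
  }
  structure(
    list(lambda_star = lambda, k = k, alpha = alpha, delta = alpha / k,
         testable = testable, risk = risk),
    class = "lamp_outcome"
  )
}

#' @export
print.lamp_outcome <- function(x, ...) {
  cat(sprintf(
    "<lamp_outcome> lambda* = %d, k = %d testable combinations, alpha = %g, delta = alpha/k = %.3g\n",
    x$lambda_star, x$k, x$alpha, x$delta
  ))
  invisible(x)
}

#' @rdname lamp_lambda_search
#' @param x A `lamp_outcome`.
#' @param ... Unused.
#' @method tidy lamp_outcome
#' @export
tidy.lamp_outcome <- function(x, ...) {
  dplyr::select(x$testable, "pattern", "support", "markers")
}

#' @rdname lamp_lambda_search
#' @method glance lamp_outcome
#' @export
glance.lamp_outcome <- function(x, ...) {
  tibble(lambda_star = x$lambda_star, k = x$k, alpha = x$alpha, delta = x$delta)
}

#' Significant marker combinations on one dataset
#'
#' Runs the support-threshold search, computes the raw log-rank p-value of
#' every testable combination, and flags those at or below the adjusted
#' threshold `delta = alpha / k`. Adjusted p-values are `min(1, raw * k)`.
#' Combinations carried by all samples (or none at risk vs none) have no
#' group separation; their p-value is defined as 1 and they are never
#' significant.
#'
#' @inheritParams lamp_lambda_search
#' @param variant Log-rank variance convention, see [logrank_statistic()].
#' @return A tibble sorted by support descending, then raw p ascending,
#'   then combination label, with columns `markers`, `pattern`, `support`,
#'   `raw_p`, `adjusted_p`, `significant`; attributes `lambda_star`, `k`,
#'   `alpha`, `delta` carry the search outcome.
#' @examples
#' spec <- simulation_spec(n_samples = 60, n_markers = 6, carrier_prob = 0.3,
#'                         planted_markers = 1:2, hazard_ratio = 6, seed = 42)
#' enumerate_significant(generate_dataset(spec))
#' @export
enumerate_significant <- function(ds, alpha = 0.05,
                                  variant = c("standard", "paper"), risk = NULL) {
  variant <- match.arg(variant)
  risk <- risk %||% build_risk_structure(ds)
  outcome <- lamp_lambda_search(ds, alpha, risk)
  res <- score_patterns(ds, outcome$testable, risk, variant)
  res$significant <- res$raw_p <= outcome$delta
  res$adjusted_p <- adjust_pvalue(res$raw_p, outcome$k)
  res <- res[c_order(-res$support, res$raw_p, res$pattern), ]
  attr(res, "lambda_star") <- outcome$lambda_star
  attr(res, "k") <- outcome$k
  attr(res, "alpha") <- outcome$alpha
  attr(res, "delta") <- outcome$delta
  res
}

# raw log-rank p for every row of a closed-pattern tibble
score_patterns <- function(ds, patterns, risk, variant) {
  time <- ds$clinical$time
  event <- ds$clinical$event
  raw_p <- vapply(patterns$carriers, function(tidx) {
    cc <- carrier_counts(time[tidx], event[tidx], risk)
    logrank_core(risk$at_risk, risk$failures, cc$at_risk, cc$failures,
                 variant = variant, warn = FALSE)[["p"]]
  }, numeric(1))
  tibble(
    markers = patterns$markers,
    pattern = patterns$pattern,
    support = patterns$support,
    raw_p = raw_p,
    adjusted_p = NA_real_,
    significant = NA
  )
}
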