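#' Risk-set structure at the distinct failure times
#'
#' Tabulates, for each distinct time at which at least one event occurs,
#' the number of samples still at risk and the number of events at that
#' time. A sample is at risk at time `t` when its observed time is `>= t`
#' (inclusive: a sample censored exactly at a failure time is counted in
#' that risk set). This structure is shared by every pattern tested on the
#' dataset and by the minimum p-value bound.
#'
#' @param x A `survlamp_dataset` or a clinical tibble with `time` and
#'   `event` columns.
#' @return A tibble of class `risk_structure` with columns `time`
#'   (increasing distinct failure times), `at_risk` and `failures`.
#' @examples
#' clin <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                        time = c(1, 1, 2), event = c(1L, 1L, 0L))
#' build_risk_structure(clin)
#' @export
build_risk_structure <- function(x) {
  clinical <- if (inherits(x, "survlamp_dataset")) x$clinical else x
  if (!is.data.frame(clinical) || !all(c("time", "event") %in% names(clinical))) {
    abort("expected a `survlamp_dataset` or a data frame with `time` and `event`.")
  }
  time <- clinical$time
  event <- clinical$event
  ft <- sort(unique(time[event == 1]))
  if (length(ft) == 0L) {
    abort("no events in the data; the log-rank risk structure is undefined.")
  }
  sorted <- sort(time)
  n_total <- length(time)
  # at risk at t_j: observed time >= t_j; findInterval with left.open counts
  # the times strictly below t_j
  at_risk <- n_total - findInterval(ft, sorted, left.open = TRUE)
  failures <- as.integer(table(factor(time[event == 1], levels = ft)))
  out <- tibble(time = ft, at_risk = as.integer(at_risk), failures = failures)
  class(out) <- c("risk_structure", class(out))
  out
}

check_risk <- function(risk) {
  if (!inherits(risk, "risk_structure")) {
    abort("expected a `risk_structure`; build one with `build_risk_structure()`.")
  }
  invisible(risk)
}

# carrier mask (logical over samples) for a marker combination; an empty
# combination is the vacuous conjunction, carried by every sample
carrier_mask <- function(ds, markers) {
  check_dataset(ds)
  markers <- unique(as.character(markers))
  unknown <- setdiff(markers, ds$marker_ids)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown marker id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(markers) == 0L) {
    return(rep(TRUE, length(ds$sample_ids)))
  }
  colSums(ds$markers[markers, , drop = FALSE]) == length(markers)
}

#' Number of samples carrying a marker combination
#'
#' Counts samples with value 1 for every marker of the combination (the
#' combination's support, the paper-trail quantity "number of
#' occurrences"). The empty combination is carried by all samples.
#'
#' @param ds A `survlamp_dataset`.
#' @param markers Character vector of marker ids.
#' @return Integer support.
#' @export
pattern_support <- function(ds, markers) {
  sum(carrier_mask(ds, markers))
}

# fast per-failure-time carrier counts for a carrier time/event split;
# exact comparisons only (failure times are copies of observed times)
carrier_counts <- function(carrier_time, carrier_event, risk) {
  ft <- risk$time
  k <- length(ft)
  if (length(carrier_time) == 0L) {
    return(list(at_risk = integer(k), failures = integer(k)))
  }
  sorted <- sort(carrier_time)
  lam <- length(carrier_time) - findInterval(ft, sorted, left.open = TRUE)
  ev <- carrier_time[carrier_event == 1L]
  n1 <- tabulate(match(ev, ft, nomatch = 0L), nbins = k)
  list(at_risk = as.integer(lam), failures = as.integer(n1))
}

#' Per-failure-time contingency tables for a marker combination
#'
#' Builds the sequence of 2x2 tables behind the log-rank test: at each
#' distinct failure time, carriers of the combination versus non-carriers,
#' failed versus still at risk.
#'
#' @param ds A `survlamp_dataset`.
#' @param markers Character vector of marker ids forming the combination.
#' @param risk Optional precomputed [build_risk_structure()] result.
#' @return A tibble of class `pattern_tables` with columns `time`,
#'   `at_risk`, `failures`, `carriers_at_risk`, `carrier_failures`.
#' @export
pattern_tables <- function(ds, markers, risk = NULL) {
  mask <- carrier_mask(ds, markers)
  risk <- risk %||% build_risk_structure(ds)
  check_risk(risk)
  cc <- carrier_counts(ds$clinical$time[mask], ds$clinical$event[mask], risk)
  out <- tibble(
    time = risk$time,
    at_risk = risk$at_risk,
    failures = risk$failures,
    carriers_at_risk = cc$at_risk,
    carrier_failures = cc$failures
  )
  class(out) <- c("pattern_tables", class(out))
  out
}

# core statistic on raw count vectors; returns c(z, chi2, p)
logrank_core <- function(Y, n, lam, n1, variant = "standard", warn = TRUE) {
  keep <- Y > 1L
  Y <- Y[keep]; n <- n[keep]; lam <- lam[keep]; n1 <- n1[keep]
  e <- n * lam / Y
  other <- if (variant == "paper") Y - lam - n + n1 else Y - lam
  v <- lam * other * n * (Y - n) / (Y^2 * (Y - 1))
  sv <- sum(v)
  if (sv <= 0) {
    if (warn) {
      warn("zero log-rank variance: the carrier split never separates the risk sets; returning p = 1.",
           class = "survlamp_degenerate")
    }
    return(c(z = 0, chi2 = 0, p = 1))
  }
  z <- sum(n1 - e) / sqrt(sv)
  c(z = z, chi2 = z^2, p = pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' Log-rank statistic and p-value from contingency tables
#'
#' Computes the log-rank statistic Z over the per-failure-time tables.
#' The observed-minus-expected carrier failures are summed over failure
#' times and normalised by the square root of the summed variances;
#' `Z^2` is referred to the chi-square distribution with 1 degree of
#' freedom. Failure times with fewer than two samples at risk contribute
#' nothing to either sum (their variance term is undefined).
#'
#' Two variance conventions are available. `"standard"` (default, used for
#' all significance decisions) is the margin-only hypergeometric variance
#' with tie correction, `V_j = l_j (Y_j - l_j) n_j (Y_j - n_j) /
#' (Y_j^2 (Y_j - 1))`, matching reference survival implementations such as
#' [survival::survdiff()]. `"paper"` replaces the factor `(Y_j - l_j)` by
#' the observed inner cell `(Y_j - l_j - n_j + n_1j)`, a variant that
#' appears in print in the source derivation of this procedure; it is
#' provided for literal reproduction only (see the package vignette).
#'
#' @param tables A [pattern_tables()] tibble.
#' @param variant `"standard"` or `"paper"` (variance convention).
#' @param warn Warn when the total variance is zero (no group separation).
#' @return A one-row tibble with `z`, `chi2`, `p_value`, `variant`. When
#'   the summed variance is zero the result is defined as `z = 0`,
#'   `p_value = 1`, with a warning of class `survlamp_degenerate`.
#' @export
logrank_statistic <- function(tables, variant = c("standard", "paper"), warn = TRUE) {
  variant <- match.arg(variant)
  if (!is.data.frame(tables) ||
      !all(c("at_risk", "failures", "carriers_at_risk", "carrier_failures") %in% names(tables))) {
    abort("expected a `pattern_tables` tibble; build one with `pattern_tables()`.")
  }
  res <- logrank_core(tables$at_risk, tables$failures,
                      tables$carriers_at_risk, tables$carrier_failures,
                      variant = variant, warn = warn)
  tibble(z = res[["z"]], chi2 = res[["chi2"]], p_value = res[["p"]], variant = variant)
}

#' Log-rank test for one marker combination
#'
#' Convenience wrapper: builds the contingency tables for the combination
#' and evaluates [logrank_statistic()].
#'
#' @inheritParams pattern_tables
#' @inheritParams logrank_statistic
#' @return A one-row tibble with `pattern`, `support`, `z`, `chi2`,
#'   `p_value`, `variant`.
#' @examples
#' ds <- generate_dataset(simulation_spec(n_samples = 40, n_markers = 3,
#'                                        carrier_prob = 0.3, seed = 1))
#' logrank_test(ds, ds$marker_ids[1])
#' @export
logrank_test <- function(ds, markers, variant = c("standard", "paper"),
                         risk = NULL, warn = TRUE) {
  variant <- match.arg(variant)
  tab <- pattern_tables(ds, markers, risk)
  res <- logrank_statistic(tab, variant, warn = warn)
  dplyr::bind_cols(
    tibble(pattern = paste(c_sort(unique(as.character(markers))), collapse = ","),
           support = pattern_support(ds, markers)),
    res
  )
}
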