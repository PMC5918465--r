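# Brute-force oracles, independent of the package's computation paths:
# risk sets by definitional loops, closed patterns by powerset enumeration,
# the minimum p-value bound by direct rational arithmetic, and the
# support-threshold search replayed over brute-force pattern counts.

# build a dataset from explicit pieces through the public API
make_dataset <- function(marker_rows, time, event, sample_ids = NULL) {
  m <- length(marker_rows)
  n <- length(time)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(n))
  markers <- tibble::tibble(marker_id = names(marker_rows))
  vals <- do.call(rbind, unname(marker_rows))
  for (j in seq_len(n)) markers[[sample_ids[j]]] <- vals[, j]
  clinical <- tibble::tibble(sample_id = sample_ids, time = time,
                             event = as.integer(event))
  align_dataset(markers, clinical)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# definitional risk sets: loops only
brute_risk <- function(time, event) {
  ft <- sort(unique(time[event == 1]))
  list(
    time = ft,
    at_risk = vapply(ft, function(t) sum(time >= t), numeric(1)),
    failures = vapply(ft, function(t) sum(time == t & event == 1), numeric(1))
  )
}

# definitional contingency tables + the printed summation formula
brute_logrank_p <- function(time, event, mask, variant = "standard") {
  rk <- brute_risk(time, event)
  num <- 0
  den <- 0
  for (j in seq_along(rk$time)) {
    t <- rk$time[j]
    Y <- rk$at_risk[j]
    n <- rk$failures[j]
    lam <- sum(mask & time >= t)
    n1 <- sum(mask & time == t & event == 1)
    if (Y <= 1) next
    e <- n * lam / Y
    other <- if (variant == "paper") Y - lam - n + n1 else Y - lam
    num <- num + (n1 - e)
    den <- den + lam * other * n * (Y - n) / (Y^2 * (Y - 1))
  }
  if (den <= 0) return(1)
  stats::pchisq(num^2 / den, df = 1, lower.tail = FALSE)
}

# minimum p-value bound by direct rational arithmetic (small Y only)
brute_bound <- function(lambda, at_risk, failures) {
  lambda <- min(lambda, max(at_risk))
  prod(ifelse(lambda <= failures,
              choose(failures, lambda) / choose(at_risk, lambda),
              1 / choose(at_risk, failures)))
}

# all closed patterns with support >= min_support via powerset enumeration
brute_closed <- function(ds, min_support) {
  G <- ds$markers
  M <- nrow(G)
  seen <- character(0)
  out <- list()
  for (code in seq_len(2^M - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(M) - 1)) > 0)
    carriers <- which(colSums(G[idx, , drop = FALSE]) == length(idx))
    if (length(carriers) < min_support) next
    key <- paste(carriers, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    closure <- which(rowSums(G[, carriers, drop = FALSE]) == length(carriers))
    out[[length(out) + 1L]] <- list(
      pattern = paste(sort(rownames(G)[closure], method = "radix"), collapse = ","),
      support = length(carriers),
      carriers = carriers
    )
  }
  out
}

# replay of the support-threshold descent over brute-force counts
brute_lambda_search <- function(ds, alpha) {
  rk <- brute_risk(ds$clinical$time, ds$clinical$event)
  max_support <- max(rowSums(ds$markers))
  stopifnot(max_support >= 2)
  lambda <- max(2, min(max_support, max(rk$at_risk)))
  repeat {
    pats <- brute_closed(ds, lambda)
    k <- length(pats)
    if (lambda > 2 && brute_bound(lambda - 1, rk$at_risk, rk$failures) <= alpha / k) {
      lambda <- lambda - 1
    } else {
      break
    }
  }
  list(lambda_star = lambda, k = k,
       patterns = sort(vapply(pats, `[[`, character(1), "pattern")))
}

# random paper-shaped instance for property tests; moderate censoring so
# the number of distinct failure times is non-trivial
random_instance <- function(seed, n_range = 15:40, m_range = 3:10,
                            prob_range = c(0.15, 0.45)) {
  withr::with_seed(seed, {
    n <- sample(n_range, 1)
    m <- sample(m_range, 1)
    p <- stats::runif(1, prob_range[1], prob_range[2])
    generate_dataset(
      simulation_spec(n_samples = n, n_markers = m, carrier_prob = p, seed = seed + 1L)
    )
  })
}

# independent reference p-value via survival::survdiff
survdiff_p <- function(time, event, mask) {
  fit <- survival::survdiff(
    survival::Surv(time, event) ~ grp,
    data = data.frame(time = time, event = event, grp = as.integer(mask))
  )
  list(chisq = fit$chisq, p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}
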