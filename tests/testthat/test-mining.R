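test_that("identical carrier columns close together; subsets stay distinct", {
  ds <- make_dataset(
    list(A = c(1, 1, 0), B = c(1, 1, 0)),
    time = 1:3, event = rep(1, 3)
  )
  pats <- closed_frequent_patterns(ds, 2)
  expect_equal(pats$pattern, "A,B")
  expect_equal(pats$support, 2L)

  ds <- make_dataset(
    list(A = c(1, 1, 1), B = c(1, 1, 0)),
    time = 1:3, event = rep(1, 3)
  )
  pats <- closed_frequent_patterns(ds, 2)
  expect_equal(pats$pattern, c("A", "A,B"))
  expect_equal(pats$support, c(3L, 2L))

  expect_equal(nrow(closed_frequent_patterns(ds, 4)), 0L)
})

test_that("the miner enumerates exactly the powerset's closed carrier sets", {
  for (seed in 1:30) {
    ds <- random_instance(seed + 700, n_range = 10:30, m_range = 3:8)
    for (minsup in c(1, 2, 3)) {
      mined <- closed_frequent_patterns(ds, minsup)
      brute <- brute_closed(ds, minsup)
      expect_setequal(mined$pattern, vapply(brute, `[[`, character(1), "pattern"))
      key <- setNames(vapply(brute, `[[`, integer(1), "support"),
                      vapply(brute, `[[`, character(1), "pattern"))
      expect_equal(unname(key[mined$pattern]), mined$support)
    }
  }
})

test_that("mined ordering is support-descending then label-lexicographic", {
  ds <- random_instance(991, n_range = 20:20, m_range = 6:6)
  pats <- closed_frequent_patterns(ds, 1)
  expect_false(is.unsorted(-pats$support))
  for (s in unique(pats$support)) {
    lab <- pats$pattern[pats$support == s]
    expect_equal(lab, sort(lab, method = "radix"))
  }
})

test_that("non-closed frequent patterns inherit their closure's p-value", {
  compared <- 0L
  for (seed in 1:10) {
    ds <- random_instance(seed + 800, n_range = 10:25, m_range = 4:6)
    # duplicate one marker column so some closure has redundant members
    G <- ds$markers
    G[2, ] <- G[1, ]
    markers <- tibble::tibble(marker_id = rownames(G))
    for (j in seq_along(ds$sample_ids)) {
      markers[[ds$sample_ids[j]]] <- as.integer(G[, j])
    }
    ds <- align_dataset(markers, ds$clinical)
    risk <- build_risk_structure(ds)
    pats <- closed_frequent_patterns(ds, 2)
    for (i in seq_len(nrow(pats))) {
      ids <- pats$markers[[i]]
      if (length(ids) < 2) next
      sub <- ids[-1]
      if (pattern_support(ds, sub) != pats$support[i]) next # different carrier set
      expect_equal(
        logrank_test(ds, sub, risk = risk, warn = FALSE)$p_value,
        logrank_test(ds, ids, risk = risk, warn = FALSE)$p_value
      )
      compared <- compared + 1L
    }
  }
  expect_gt(compared, 0L)
})

test_that("a one-marker universe is testable when its support allows", {
  ds <- make_dataset(
    list(A = c(1, 1, 1, 0, 0, 0, 0, 0)),
    time = 1:8, event = rep(1, 8)
  )
  out <- lamp_lambda_search(ds, alpha = 0.5)
  expect_gte(out$k, 1L)
  expect_lte(out$lambda_star, 3L)
  expect_true("A" %in% out$testable$pattern)

  singletons <- make_dataset(
    list(A = c(1, 0, 0), B = c(0, 1, 0)),
    time = 1:3, event = rep(1, 3)
  )
  expect_error(lamp_lambda_search(singletons), class = "survlamp_untestable")
})

test_that("the threshold search matches a brute-force scan over all thresholds", {
  for (seed in 1:25) {
    ds <- random_instance(seed + 900, n_range = 10:30, m_range = 3:7)
    if (max(rowSums(ds$markers)) < 2) next
    for (alpha in c(0.05, 0.3)) {
      got <- lamp_lambda_search(ds, alpha)
      want <- brute_lambda_search(ds, alpha)
      expect_equal(got$lambda_star, want$lambda_star)
      expect_equal(got$k, want$k)
      expect_setequal(got$testable$pattern, want$patterns)
    }
  }
})

test_that("search upholds its pruning guarantee and k is monotone in lambda", {
  for (seed in 1:10) {
    ds <- random_instance(seed + 1000, n_range = 12:30, m_range = 3:7)
    if (max(rowSums(ds$markers)) < 2) next
    risk <- build_risk_structure(ds)
    out <- lamp_lambda_search(ds, 0.05, risk)
    expect_gte(out$lambda_star, 2L)
    expect_equal(out$delta, 0.05 / out$k)
    expect_true(all(out$testable$support >= out$lambda_star))
    if (out$lambda_star > 2L) {
      expect_gt(min_pvalue_bound(out$lambda_star - 1L, risk), 0.05 / out$k)
    }
    ks <- vapply(2:max(3, out$lambda_star + 1), function(l) {
      nrow(closed_frequent_patterns(ds, l))
    }, integer(1))
    expect_false(is.unsorted(rev(ks)))
  }
})

test_that("significant enumeration adjusts, flags and orders results", {
  spec <- simulation_spec(
    n_samples = 200, n_markers = 8, carrier_prob = 0.3,
    planted_markers = 1:2, hazard_ratio = 8, seed = 77
  )
  ds <- generate_dataset(spec)
  res <- enumerate_significant(ds, alpha = 0.05)
  k <- attr(res, "k")
  expect_equal(nrow(res), k)
  expect_equal(res$adjusted_p, pmin(1, res$raw_p * k))
  expect_equal(res$significant, res$raw_p <= attr(res, "delta"))
  expect_false(is.unsorted(-res$support))
  ties <- split(res$raw_p, res$support)
  expect_true(all(vapply(ties, function(p) !is.unsorted(p), logical(1))))
  # the planted pair separates survival strongly enough to be flagged
  planted_ids <- ds$marker_ids[1:2]
  planted <- res[vapply(res$markers, function(m) all(planted_ids %in% m), logical(1)), ]
  expect_gte(nrow(planted), 1L)
  expect_true(any(planted$significant))
})

test_that("patterns carried by every sample are never declared significant", {
  ds <- make_dataset(
    list(A = c(1, 1, 1, 1), B = c(1, 1, 0, 0)),
    time = 1:4, event = rep(1, 4)
  )
  res <- enumerate_significant(ds, alpha = 0.9)
  row <- res[res$pattern == "A", ]
  expect_equal(row$raw_p, 1)
  expect_false(row$significant)
})
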