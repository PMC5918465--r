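test_that("risk structure counts at-risk and failing samples by definition", {
  rs <- build_risk_structure(tibble::tibble(time = c(1, 2, 3), event = c(1L, 1L, 1L)))
  expect_equal(rs$time, c(1, 2, 3))
  expect_equal(rs$at_risk, c(3L, 2L, 1L))
  expect_equal(rs$failures, c(1L, 1L, 1L))

  # tied failures; a censored sample contributes no failure time
  rs <- build_risk_structure(tibble::tibble(time = c(1, 1, 2), event = c(1L, 1L, 0L)))
  expect_equal(rs$time, 1)
  expect_equal(rs$at_risk, 3L)
  expect_equal(rs$failures, 2L)

  # sample censored before the only failure time has left the risk set
  rs <- build_risk_structure(tibble::tibble(time = c(5, 10), event = c(0L, 1L)))
  expect_equal(rs$time, 10)
  expect_equal(rs$at_risk, 1L)
  expect_equal(rs$failures, 1L)

  expect_error(
    build_risk_structure(tibble::tibble(time = c(1, 2), event = c(0L, 0L))),
    "no events"
  )
})

test_that("risk structure matches the definitional loops on random data", {
  for (seed in 1:20) {
    ds <- random_instance(seed)
    rs <- build_risk_structure(ds)
    br <- brute_risk(ds$clinical$time, ds$clinical$event)
    expect_equal(rs$time, br$time)
    expect_equal(as.numeric(rs$at_risk), br$at_risk)
    expect_equal(as.numeric(rs$failures), br$failures)
  }
})

test_that("support is the conjunction count, with the empty pattern vacuous", {
  ds <- make_dataset(
    list(A = c(1, 1, 0, 1), B = c(1, 0, 0, 1), C = c(1, 0, 1, 1)),
    time = 1:4, event = rep(1, 4)
  )
  expect_equal(pattern_support(ds, "A"), 3L)
  expect_equal(pattern_support(ds, c("A", "B")), 2L)
  expect_equal(pattern_support(ds, character(0)), 4L)
  expect_error(pattern_support(ds, "nope"), "unknown marker")
})

test_that("pattern tables follow the carrier definitions at each failure time", {
  ds <- make_dataset(
    list(A = c(1, 1, 0, 0), B = c(0, 0, 0, 0), C = c(1, 1, 1, 1)),
    time = 1:4, event = rep(1, 4)
  )
  tab <- pattern_tables(ds, "A")
  expect_equal(tab$carriers_at_risk, c(2L, 1L, 0L, 0L))
  expect_equal(tab$carrier_failures, c(1L, 1L, 0L, 0L))

  nobody <- pattern_tables(ds, "B")
  expect_true(all(nobody$carriers_at_risk == 0L))
  expect_true(all(nobody$carrier_failures == 0L))

  everybody <- pattern_tables(ds, "C")
  expect_equal(everybody$carriers_at_risk, everybody$at_risk)
  expect_equal(everybody$carrier_failures, everybody$failures)
})

test_that("the statistic reproduces hand arithmetic on a single table", {
  tab <- tibble::tibble(time = 1, at_risk = 4L, failures = 1L,
                        carriers_at_risk = 2L, carrier_failures = 1L)
  res <- logrank_statistic(tab)
  # E = 0.5, V = 2*2*1*3/(16*3) = 0.25, Z = 0.5/0.5 = 1
  expect_equal(res$z, 1)
  expect_equal(res$chi2, 1)
  expect_equal(res$p_value, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.3173)
})

test_that("the printed variance variant uses the observed inner cell", {
  tab <- tibble::tibble(time = 1, at_risk = 5L, failures = 2L,
                        carriers_at_risk = 2L, carrier_failures = 1L)
  # E = 0.8; standard V = 2*3*2*3/(25*4) = 0.36; printed V = 2*2*2*3/(25*4) = 0.24
  std <- logrank_statistic(tab, "standard")
  pap <- logrank_statistic(tab, "paper")
  expect_equal(std$z, 0.2 / sqrt(0.36))
  expect_equal(pap$z, 0.2 / sqrt(0.24))
  expect_gt(pap$chi2, std$chi2)
})

test_that("zero-variance splits return the defined degenerate result", {
  ds <- make_dataset(
    list(A = c(0, 0, 0), B = c(1, 1, 1)),
    time = 1:3, event = rep(1, 3)
  )
  expect_warning(res <- logrank_test(ds, "A"), class = "survlamp_degenerate")
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_warning(res <- logrank_test(ds, "B"), class = "survlamp_degenerate")
  expect_equal(res$p_value, 1)
})

test_that("complementing the carrier set leaves chi-square and p unchanged", {
  for (seed in 1:15) {
    ds <- random_instance(seed + 100)
    m <- ds$marker_ids[1]
    mask <- colSums(ds$markers[m, , drop = FALSE]) == 1
    if (all(mask) || !any(mask)) next
    risk <- build_risk_structure(ds)
    tab <- pattern_tables(ds, m, risk)
    flipped <- tab
    flipped$carriers_at_risk <- tab$at_risk - tab$carriers_at_risk
    flipped$carrier_failures <- tab$failures - tab$carrier_failures
    a <- logrank_statistic(tab, warn = FALSE)
    b <- logrank_statistic(flipped, warn = FALSE)
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
  }
})

test_that("the statistic agrees with brute-force table construction", {
  for (seed in 1:15) {
    ds <- random_instance(seed + 200)
    markers <- ds$marker_ids[seq_len(min(2, length(ds$marker_ids)))]
    mask <- colSums(ds$markers[markers, , drop = FALSE]) == length(markers)
    p_pkg <- logrank_test(ds, markers, warn = FALSE)$p_value
    p_brute <- brute_logrank_p(ds$clinical$time, ds$clinical$event, mask)
    expect_equal(p_pkg, p_brute, tolerance = 1e-12)
  }
})

test_that("null p-values are approximately uniform without censoring", {
  n <- 100
  reps <- 2000
  pvals <- withr::with_seed(424242, {
    vapply(seq_len(reps), function(i) {
      time <- rexp(n, 0.02)
      mask <- rbinom(n, 1, 0.5) == 1
      brute <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                              time = time, event = rep(1L, n))
      risk <- build_risk_structure(brute)
      cc_tab <- tibble::tibble(
        time = risk$time, at_risk = risk$at_risk, failures = risk$failures,
        carriers_at_risk = vapply(risk$time, function(t) sum(mask & time >= t), numeric(1)),
        carrier_failures = vapply(risk$time, function(t) sum(mask & time == t), numeric(1))
      )
      logrank_statistic(cc_tab, warn = FALSE)$p_value
    }, numeric(1))
  })
  ks <- max(abs(sort(pvals) - (seq_len(reps)) / reps))
  expect_lt(ks, 0.1)
})

test_that("logrank_test output labels the pattern and support", {
  ds <- make_dataset(
    list(B = c(1, 1, 0, 1), A = c(1, 1, 0, 0)),
    time = 1:4, event = rep(1, 4)
  )
  res <- logrank_test(ds, c("B", "A"))
  expect_equal(res$pattern, "A,B")
  expect_equal(res$support, 2L)
})
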