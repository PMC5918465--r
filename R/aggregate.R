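#' Chunked analysis with an aggregated correction factor
#'
#' Runs the full procedure independently on consecutive marker chunks
#' (each chunk gets its own support-threshold search, correction factor
#' `k_i`, and candidate set significant at `alpha / k_i`), then aggregates:
#' the total correction factor is `total_k = sum(k_i)`, and a candidate is
#' finally significant only when `raw_p * total_k < alpha` (strict).
#' Adjusted p-values in the report use `total_k`. Chunks in which no
#' marker reaches support 2 contribute `k_i = 0` and no candidates, with a
#' warning; if every chunk is untestable the run errors.
#'
#' Combinations spanning two chunks are unreachable by construction —
#' chunking trades that exhaustiveness for bounded runtime, and results
#' near chunk boundaries are sensitive to the chunk size.
#'
#' @param ds A `survlamp_dataset`.
#' @param alpha Target family-wise error rate (default 0.05).
#' @param chunk_size Markers per chunk (default 250).
#' @param variant Log-rank variance convention, see [logrank_statistic()].
#' @return A `lamp_report`: list with `per_chunk` (tibble of `chunk`,
#'   `lambda_star`, `k`), `total_k`, `alpha`, `variant`, and `results`
#'   (candidate combinations re-adjusted with `total_k`, sorted by support
#'   descending, raw p ascending, label).
#' @examples
#' spec <- simulation_spec(n_samples = 60, n_markers = 6, carrier_prob = 0.3,
#'                         planted_markers = 1:2, hazard_ratio = 6, seed = 42)
#' run_chunked(generate_dataset(spec))
#' @export
run_chunked <- function(ds, alpha = 0.05, chunk_size = 250,
                        variant = c("standard", "paper")) {
  variant <- match.arg(variant)
  check_dataset(ds)
  risk <- build_risk_structure(ds)
  chunks <- chunk_markers(ds, chunk_size)
  per_chunk <- vector("list", length(chunks))
  candidates <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    outcome <- tryCatch(
      lamp_lambda_search(chunks[[i]], alpha, risk),
      survlamp_untestable = function(cnd) NULL
    )
    if (is.null(outcome)) {
      warn(sprintf("chunk %d: no marker with support >= 2; contributing k = 0.", i))
      per_chunk[[i]] <- tibble(chunk = i, lambda_star = NA_integer_, k = 0L)
      next
    }
    per_chunk[[i]] <- tibble(chunk = i, lambda_star = outcome$lambda_star, k = outcome$k)
    scored <- score_patterns(chunks[[i]], outcome$testable, risk, variant)
    scored <- scored[scored$raw_p <= outcome$delta, , drop = FALSE]
    if (nrow(scored) > 0L) {
      scored$chunk <- i
      candidates[[i]] <- scored
    }
  }
  per_chunk <- dplyr::bind_rows(per_chunk)
  total_k <- sum(per_chunk$k)
  if (total_k == 0L) {
    abort("no chunk produced a testable combination.", class = "survlamp_untestable")
  }
  results <- dplyr::bind_rows(candidates)
  if (nrow(results) == 0L) {
    results <- tibble(
      markers = list(), pattern = character(), support = integer(),
      raw_p = numeric(), adjusted_p = numeric(), significant = logical(),
      chunk = integer()
    )
  } else {
    results$adjusted_p <- adjust_pvalue(results$raw_p, total_k)
    results$significant <- results$raw_p * total_k < alpha
    results <- results[c_order(-results$support, results$raw_p, results$pattern), ]
  }
  structure(
    list(per_chunk = per_chunk, total_k = total_k, alpha = alpha,
         variant = variant, results = results),
    class = "lamp_report"
  )
}

#' @export
print.lamp_report <- function(x, ...) {
  cat(sprintf(
    "<lamp_report> %d chunk(s), total correction factor k = %d, alpha = %g\n",
    nrow(x$per_chunk), x$total_k, x$alpha
  ))
  cat(sprintf("%d candidate combination(s), %d significant after total-k correction\n",
              nrow(x$results), sum(x$results$significant)))
  if (nrow(x$results) > 0L) {
    print(head(dplyr::select(x$results, "pattern", "support", "raw_p", "adjusted_p",
                             "significant"), 10))
  }
  invisible(x)
}

#' @rdname run_chunked
#' @param x A `lamp_report`.
#' @param ... Unused.
#' @method tidy lamp_report
#' @export
tidy.lamp_report <- function(x, ...) {
  dplyr::select(x$results, "pattern", "support", "raw_p", "adjusted_p",
                "significant", "chunk")
}

#' @rdname run_chunked
#' @method glance lamp_report
#' @export
glance.lamp_report <- function(x, ...) {
  tibble(
    n_chunks = nrow(x$per_chunk),
    total_k = x$total_k,
    alpha = x$alpha,
    n_candidates = nrow(x$results),
    n_significant = sum(x$results$significant)
  )
}

#' Write an analysis report to TSV
#'
#' Writes the candidate combinations of a [run_chunked()] report as a
#' deterministic tab-separated table (header
#' `combination support raw_p adjusted_p significant chunk`; combination
#' labels are comma-joined sorted marker ids; p-values printed with 6
#' significant digits). Two runs on the same input produce byte-identical
#' files.
#'
#' @param report A `lamp_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  if (!inherits(report, "lamp_report")) {
    abort("expected a `lamp_report` from `run_chunked()`.")
  }
  res <- report$results
  out <- tibble(
    combination = res$pattern,
    support = res$support,
    raw_p = formatC(res$raw_p, digits = 6, format = "g"),
    adjusted_p = formatC(res$adjusted_p, digits = 6, format = "g"),
    significant = res$significant,
    chunk = res$chunk
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Path to a results file.
#' @return A tibble with columns `combination`, `support`, `raw_p`,
#'   `adjusted_p`, `significant`, `chunk`.
#' @export
read_results <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      combination = readr::col_character(),
      support = readr::col_integer(),
      raw_p = readr::col_double(),
      adjusted_p = readr::col_double(),
      significant = readr::col_logical(),
      chunk = readr::col_integer()
    ),
    progress = FALSE
  )
}
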