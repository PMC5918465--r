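#' Combine binarized markers and clinical data into an analysis dataset
#'
#' Matches the sample ids of a binarized marker matrix against a clinical
#' table and returns the container the mining and testing functions work
#' on. Sample order of the clinical table is canonical: it fixes the
#' column order of the stored marker matrix, so downstream contingency
#' tables and output files are deterministic.
#'
#' @param markers Binarized marker tibble ([binarize()] output): a
#'   `marker_id` column plus one 0/1 column per sample.
#' @param clinical Clinical tibble ([read_clinical()] output).
#' @param policy `"intersect"` keeps samples present in both inputs (error
#'   if the intersection is empty); `"strict"` errors on any mismatch.
#' @return A `survlamp_dataset`: list with `marker_ids`, `sample_ids`, a
#'   logical marker-by-sample matrix `markers`, and the aligned `clinical`
#'   tibble.
#' @examples
#' markers <- tibble::tibble(marker_id = "g1", a = 1, b = 0, c = 1)
#' clinical <- tibble::tibble(sample_id = c("b", "c", "d"),
#'                            time = c(5, 10, 2), event = c(1L, 0L, 1L))
#' align_dataset(markers, clinical)
#' @export
align_dataset <- function(markers, clinical, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  check_binary_frame(markers)
  if (!is.data.frame(clinical) || !all(c("sample_id", "time", "event") %in% names(clinical))) {
    abort("`clinical` must have columns sample_id, time, event.")
  }
  marker_samples <- names(markers)[-1]
  clin_samples <- clinical$sample_id
  if (policy == "strict") {
    missing_clin <- setdiff(marker_samples, clin_samples)
    missing_mark <- setdiff(clin_samples, marker_samples)
    if (length(missing_clin) > 0L || length(missing_mark) > 0L) {
      abort(sprintf(
        "strict alignment failed; only in marker matrix: [%s]; only in clinical: [%s]",
        paste(missing_clin, collapse = ", "), paste(missing_mark, collapse = ", ")
      ))
    }
  }
  keep <- clin_samples[clin_samples %in% marker_samples]
  if (length(keep) == 0L) {
    abort("no samples shared between marker matrix and clinical table.")
  }
  clinical <- clinical[match(keep, clinical$sample_id), c("sample_id", "time", "event")]
  mat <- as.matrix(markers[, keep, drop = FALSE]) > 0
  rownames(mat) <- markers$marker_id
  colnames(mat) <- keep
  new_survlamp_dataset(mat, as_tibble(clinical))
}

new_survlamp_dataset <- function(marker_matrix, clinical) {
  stopifnot(is.logical(marker_matrix), ncol(marker_matrix) == nrow(clinical))
  structure(
    list(
      marker_ids = rownames(marker_matrix),
      sample_ids = clinical$sample_id,
      markers = marker_matrix,
      clinical = clinical
    ),
    class = "survlamp_dataset"
  )
}

#' @export
print.survlamp_dataset <- function(x, ...) {
  cat(sprintf(
    "<survlamp_dataset> %d markers x %d samples; %d events, %d censored\n",
    length(x$marker_ids), length(x$sample_ids),
    sum(x$clinical$event == 1L), sum(x$clinical$event == 0L)
  ))
  invisible(x)
}

#' @export
dim.survlamp_dataset <- function(x) dim(x$markers)

#' Split a dataset into marker chunks
#'
#' Partitions the markers into consecutive chunks of `chunk_size` in their
#' original order (the last chunk may be smaller); every chunk shares the
#' full clinical table. Chunked runs trade exhaustiveness across chunk
#' boundaries for tractability; see [run_chunked()].
#'
#' @param ds A `survlamp_dataset`.
#' @param chunk_size Markers per chunk (default 250).
#' @return A list of `survlamp_dataset` objects.
#' @export
chunk_markers <- function(ds, chunk_size = 250) {
  check_dataset(ds)
  if (!is.numeric(chunk_size) || length(chunk_size) != 1L || chunk_size < 1) {
    abort("`chunk_size` must be a positive integer.")
  }
  chunk_size <- as.integer(chunk_size)
  m <- length(ds$marker_ids)
  idx <- split(seq_len(m), ceiling(seq_len(m) / chunk_size))
  purrr::map(unname(idx), function(i) {
    new_survlamp_dataset(ds$markers[i, , drop = FALSE], ds$clinical)
  })
}

#' Export the binarized matrix as an itemset-miner transaction database
#'
#' Writes one line per sample listing the (1-based) indices of the markers
#' it carries, space-separated — the de-facto input format of external
#' frequent-itemset miners such as LCM, useful for cross-checking the
#' built-in miner.
#'
#' @param ds A `survlamp_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_transactions <- function(ds, path) {
  check_dataset(ds)
  lines <- vapply(seq_along(ds$sample_ids), function(j) {
    paste(which(ds$markers[, j]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

check_dataset <- function(ds) {
  if (!inherits(ds, "survlamp_dataset")) {
    abort("expected a `survlamp_dataset`; build one with `align_dataset()`.")
  }
  invisible(ds)
}
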