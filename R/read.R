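#' Read a marker-by-sample score matrix from TSV
#'
#' Reads a tab-separated table whose first row holds sample ids and whose
#' first column holds marker ids (e.g. gene symbols), with the remaining
#' cells continuous scores such as per-gene median-centred z-scores of
#' expression. The table is validated strictly: duplicate marker or sample
#' ids and non-numeric cells are hard errors that name the offending
#' id / position, rather than silent repairs.
#'
#' @param path Path to a TSV file. First header field is ignored (it labels
#'   the marker column); remaining header fields are sample ids.
#' @param missing Token marking a missing score (default `"NA"`). Missing
#'   scores are kept as `NA` and binarize to 0 (non-carrier).
#' @return A tibble with a `marker_id` character column followed by one
#'   numeric column per sample, rows and columns in file order.
#' @seealso [binarize()], [read_clinical()], [align_dataset()]
#' @export
read_score_matrix <- function(path, missing = "NA") {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE
  )
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    abort(sprintf("'%s': need a header row of sample ids plus at least one marker row.", path))
  }
  sample_ids <- as.character(raw[1, -1])
  marker_ids <- as.character(raw[[1]][-1])
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicated sample id(s) in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  dup <- unique(marker_ids[duplicated(marker_ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicated marker id(s) in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  cells <- as.matrix(raw[-1, -1])
  cells[cells %in% missing] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-numeric cell '%s' at marker '%s' (row %d), sample '%s' (column %d) in '%s'",
      cells[bad[1, 1], bad[1, 2]], marker_ids[bad[1, 1]], bad[1, 1] + 1L,
      sample_ids[bad[1, 2]], bad[1, 2] + 1L, path
    ))
  }
  out <- as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble(marker_id = marker_ids), out)
}

#' Binarize a score matrix into carrier calls
#'
#' Thresholds continuous scores into 0/1 carrier indicators. The default
#' reproduces the "highly expressed" coding for expression z-scores: a
#' sample carries a marker when its z-score is strictly greater than 2.
#' `direction = "less"` supports low-expression codings (e.g. z < -0.5).
#' Missing scores are conservatively coded 0 (non-carrier).
#'
#' @param scores A score tibble as returned by [read_score_matrix()]
#'   (`marker_id` column plus one numeric column per sample).
#' @param threshold Finite numeric cut point (default 2).
#' @param direction `"greater"` (carrier iff score > threshold, strict) or
#'   `"less"` (carrier iff score < threshold, strict).
#' @return A tibble of the same shape with integer 0/1 sample columns.
#' @examples
#' scores <- tibble::tibble(marker_id = c("g1", "g2"), s1 = c(2.1, 2.0), s2 = c(-1, 3))
#' binarize(scores)
#' @export
binarize <- function(scores, threshold = 2, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number.")
  }
  check_score_frame(scores)
  vals <- as.matrix(scores[, -1, drop = FALSE])
  calls <- if (direction == "greater") vals > threshold else vals < threshold
  calls[is.na(calls)] <- FALSE
  out <- as_tibble(as.data.frame(array(as.integer(calls), dim = dim(calls))),
                   .name_repair = "minimal")
  names(out) <- names(scores)[-1]
  dplyr::bind_cols(scores[, 1, drop = FALSE], out)
}

#' Read a clinical survival table from TSV
#'
#' Expects a header `sample_id`, `time`, `event`: observed survival time in
#' months (event or censoring, strictly positive) and the event indicator
#' (1 = event occurred, 0 = censored). Malformed rows are hard errors
#' reported with their line number.
#'
#' @param path Path to the clinical TSV file.
#' @return A tibble with columns `sample_id` (character), `time` (double),
#'   `event` (integer 0/1), rows in file order.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE
  )
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(raw))) {
    abort(sprintf("'%s' must have columns %s.", path, paste(need, collapse = ", ")))
  }
  time <- suppressWarnings(as.numeric(raw$time))
  event <- suppressWarnings(as.numeric(raw$event))
  bad <- which(is.na(time) | !is.finite(time) | time <= 0 |
                 is.na(event) | !(event %in% c(0, 1)))
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed clinical row at line %d of '%s' (sample '%s'): time must be > 0 and event must be 0 or 1",
      bad[1] + 1L, path, raw$sample_id[bad[1]]
    ))
  }
  dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicated sample id(s) in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  tibble(sample_id = raw$sample_id, time = time, event = as.integer(event))
}

#' Write a binary marker matrix to TSV
#'
#' Inverse of [read_score_matrix()] for binarized matrices; writing and
#' re-reading reproduces the matrix exactly.
#'
#' @param markers A binarized marker tibble ([binarize()] output).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(markers, path) {
  check_score_frame(markers)
  readr::write_tsv(markers, path, progress = FALSE)
  invisible(path)
}

# shared validation for marker/score tibbles
check_score_frame <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2L || names(x)[1] != "marker_id") {
    abort("expected a data frame with a `marker_id` first column plus one column per sample.")
  }
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    abort("all sample columns must be numeric.")
  }
  invisible(x)
}

check_binary_frame <- function(x) {
  check_score_frame(x)
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    abort("marker matrix must contain only 0/1 values; binarize scores first.")
  }
  invisible(x)
}
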