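#' Write a per-cell summary table to CSV
#'
#' Rows must be homogeneous (identical column sets); column order is kept
#' stable so diffs between runs are meaningful.
#'
#' @param records A tibble/data frame (one row per cell), or a list of
#'   one-row tibbles with identical columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_summary_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- as_tibble(records)
  } else if (is.list(records)) {
    if (length(records) == 0L) {
      abort("empty record list with unknown schema; pass a zero-row tibble instead.",
            class = "dopaphys_type_error")
    }
    cols <- lapply(records, names)
    if (!all(purrr::map_lgl(cols, identical, cols[[1L]]))) {
      abort("records are heterogeneous: differing column sets.",
            class = "dopaphys_type_error")
    }
    df <- dplyr::bind_rows(records)
  } else {
    abort("records must be a data frame or list of one-row tibbles.",
          class = "dopaphys_type_error")
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path), class = "dopaphys_format_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
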