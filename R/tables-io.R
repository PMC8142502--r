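#' Read and write feature matrices and prediction logs
#'
#' Feature matrices (one row per protein, `id` first column) and prediction
#' logs are stored as delimiter-separated text with a single header row.
#' Writing refuses non-finite values — padded or NA rows would silently
#' corrupt downstream cross-validation — and `read_feature_table()`
#' round-trips ids, column names and values at full stored precision.
#'
#' @param data Tibble whose first column identifies the row (`id`).
#' @param path File path.
#' @param delim Field delimiter (tab by default).
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- tibble::tibble(id = c("p1", "p2"), f1 = c(0.25, 1), f2 = c(1e-9, 0))
#' write_feature_table(m, tf)
#' read_feature_table(tf)
#' @export
write_feature_table <- function(data, path, delim = "\t") {
  stopifnot(is.data.frame(data), ncol(data) >= 1L)
  num <- vapply(data, is.numeric, logical(1))
  for (j in which(num)) {
    bad <- which(!is.finite(data[[j]]))
    if (length(bad) > 0L) {
      stop("non-finite value at row ", bad[1], ", column '",
           names(data)[j], "'", call. = FALSE)
    }
  }
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(out) == 0L) stop("malformed header in ", path, call. = FALSE)
  out
}
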