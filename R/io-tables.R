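#' Read and write concentration / shift matrices as CSV
#'
#' Both tables are CSV files with a header row and a leading `sample_id`
#' column; concentration tables carry one column per component (uM) plus
#' `pH` and `T` (K), shift tables one ppm column per spin system (blank
#' cells mark absent passive metabolites). Shifts are written with 6
#' decimals of ppm.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_concentration_matrix <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_concentration_matrix <- function(path) {
  if (!file.exists(path)) stop("read_concentration_matrix: file not found: ",
                               path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("read_concentration_matrix: missing sample_id column")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' @rdname table_io
#' @export
write_shift_matrix <- function(x, path) {
  out <- x
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) {
    ifelse(is.na(col), "", sprintf("%.6f", col))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_shift_matrix <- function(path) {
  if (!file.exists(path)) stop("read_shift_matrix: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) {
    stop("read_shift_matrix: missing sample_id column")
  }
  df$sample_id <- as.character(df$sample_id)
  df
}
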