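#' Read a BED3 file
#'
#' @param path path to a tab-separated file with chrom, start, end (no header).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  validate_intervals(df, what = path)
  df
}

#' Write a BED3 file
#'
#' @param df BED-like data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(df, path) {
  validate_intervals(df)
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a headered TSV
#'
#' Thin wrappers fixing the dialect used by every table in the package
#' (tab-separated, header row, no quoting, no row names).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
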