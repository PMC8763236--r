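#' Write insertion calls (or any pipeline table) as TSV
#'
#' Coordinates are 1-based inclusive; columns are written with a header
#' and no quoting so the files diff cleanly across timepoints.
#'
#' @param x Data frame (e.g. [call_insertions()] output or a
#'   `trajectory_table`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_calls()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_calls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
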