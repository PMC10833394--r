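# Plain-text grid serialization used by the command-line front-end.

#' Write a numeric grid as tab-separated text
#'
#' @param mat numeric matrix (or [ScatteringPlane-class], whose intensities
#'   are written).
#' @param path output path.
#' @export
writeGridTSV <- function(mat, path) {
  if (is(mat, "ScatteringPlane")) mat <- intensities(mat)
  utils::write.table(format(mat, digits = 12, trim = TRUE), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a numeric grid written by [writeGridTSV()]
#' @param path file path.
#' @return numeric matrix.
#' @export
readGridTSV <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
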