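# Calibration table TSV I/O (2 columns: resolution_bin, target_min_value).

#' Read / write a calibration table as TSV
#'
#' @param path TSV path with columns resolution_bin and target_min_value.
#' @return A \linkS4class{CalibrationTable} / \code{path} invisibly.
#' @export
readCalibrationTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  for (f in c("resolution_bin", "target_min_value")) {
    if (!f %in% names(df))
      lbValidationError(sprintf("calibration TSV is missing column '%s'", f))
  }
  ord <- order(df$resolution_bin)
  CalibrationTable(df$resolution_bin[ord], df$target_min_value[ord])
}

#' @rdname readCalibrationTable
#' @param table a \linkS4class{CalibrationTable}.
#' @export
writeCalibrationTable <- function(table, path) {
  stopifnot(is(table, "CalibrationTable"))
  utils::write.table(
    data.frame(resolution_bin = table@resolutionBins,
               target_min_value = table@targetMinValue),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
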