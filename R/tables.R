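#' Write result tables as CSV
#'
#' Every table is written with a header row, stable column order and
#' RFC-4180 quoting ("." decimal separator, UTF-8). Re-reading with
#' [utils::read.csv()] reproduces integer fields exactly.
#'
#' @param tables Named list of data frames; names become file stems.
#' @param dir Destination directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_tables <- function(tables, dir) {
  if (!is.list(tables) || is.null(names(tables)) ||
      any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list of data frames", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths[nm] <- path
  }
  paths
}
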