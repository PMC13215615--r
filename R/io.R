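#' Write a morphometry table as TSV with a JSON manifest sidecar
#'
#' Missing metric values are written as empty fields. The region manifest
#' is written next to the table as `<path>.manifest.json` unless
#' `manifest_path` is given.
#'
#' @param table a `morpho_table`.
#' @param path output TSV path.
#' @param manifest_path optional manifest JSON path.
#' @return `path`, invisibly.
#' @export
write_morpho <- function(table, path, manifest_path = NULL) {
  if (is.null(manifest_path)) manifest_path <- paste0(path, ".manifest.json")
  utils::write.table(as.data.frame(table), path, sep = "\t", na = "",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table_manifest(table), manifest_path, digits = NA)
  invisible(path)
}

#' Read a morphometry table written by [write_morpho()]
#'
#' @param path TSV path.
#' @param manifest_path manifest JSON path (default sidecar).
#' @return a `morpho_table`.
#' @export
read_morpho <- function(path, manifest_path = NULL) {
  if (is.null(manifest_path)) manifest_path <- paste0(path, ".manifest.json")
  man <- if (file.exists(manifest_path)) {
    as.data.frame(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
  } else region_manifest()
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = c(participant_id = "character",
                                         site = "character"))
  as_morpho_table(df, man)
}
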