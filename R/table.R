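#' Construct a morphometry table
#'
#' The universal exchange object: one row per participant, covariate columns
#' (`participant_id`, `site`, `group`, `subtype`, `age`, `bmi`, `icv`)
#' followed by one column per manifest metric. Missing metric values are
#' `NA`, never 0; covariates must be complete.
#'
#' @param df data.frame with the covariate and metric columns.
#' @param manifest region manifest describing the metric columns
#'   (default [region_manifest()]).
#' @return a `morpho_table` (data.frame subclass with a `manifest` attribute).
#' @export
as_morpho_table <- function(df, manifest = region_manifest()) {
  req <- c("participant_id", "site", "group", "subtype", "age", "bmi", "icv")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing covariate columns: ", paste(miss, collapse = ", "))
  metrics <- setdiff(intersect(manifest$metric, names(df)), req)
  unknown <- setdiff(setdiff(names(df), req), manifest$metric)
  if (length(unknown))
    stop("metric columns not in manifest: ", paste(unknown, collapse = ", "))
  if (!all(df$group %in% c("AN", "HC")))
    stop("group must be AN or HC")
  if (!all(df$subtype %in% c("AN-R", "AN-BP", "none")))
    stop("subtype must be AN-R, AN-BP or none")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be > 0")
  if (any(!is.finite(df$bmi)) || any(df$bmi <= 0)) stop("bmi must be > 0")
  if (any(!is.finite(df$icv)) || any(df$icv <= 0)) stop("icv must be > 0")
  df <- df[, c(req, metrics), drop = FALSE]
  df$site <- as.character(df$site)
  attr(df, "manifest") <- manifest
  class(df) <- c("morpho_table", "data.frame")
  df
}

#' @export
`[.morpho_table` <- function(x, ...) {
  man <- attr(x, "manifest")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "manifest") <- man
    class(out) <- unique(c("morpho_table", class(out)))
  }
  out
}

#' @export
print.morpho_table <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("<morpho_table> %d participants, %d metric columns\n",
              nrow(x), sum(man$metric %in% names(x))))
  cat(sprintf("  sites: %s\n", paste(unique(x$site), collapse = ", ")))
  tb <- table(x$group)
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Manifest of a morphometry table
#' @param table a `morpho_table`.
#' @return the region manifest attached to the table.
#' @export
table_manifest <- function(table) {
  man <- attr(table, "manifest")
  if (is.null(man)) man <- region_manifest()
  man
}

# Matrix of metric columns (participants x metrics).
metric_matrix <- function(table, metrics = NULL) {
  man <- table_manifest(table)
  if (is.null(metrics)) metrics <- intersect(man$metric, names(table))
  M <- as.matrix(as.data.frame(table)[, metrics, drop = FALSE])
  rownames(M) <- NULL
  M
}

# Rows carrying subtype labels, for AN-R vs AN-BP analyses.
subtype_rows <- function(table) {
  table[table$group == "AN" & table$subtype %in% c("AN-R", "AN-BP"), ,
        drop = FALSE]
}
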