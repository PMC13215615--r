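#' @keywords internal
dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

#' @keywords internal
sv_structures <- c("thalamus", "caudate", "putamen", "pallidum",
                   "hippocampus", "amygdala", "accumbens")

#' Region manifest for surface-based morphometry metrics
#'
#' Catalogue of the metric columns handled by the package: 34 Desikan-Killiany
#' cortical regions per hemisphere for thickness (CT, mm) and surface area
#' (SA, mm2), subcortical volumes (SV, mm3) for 7 bilateral structures plus
#' the lateral ventricles, and the global metrics (mean CT per hemisphere,
#' total SA, intracranial volume).
#'
#' The lateral ventricles take part in group comparisons and classification
#' (`mega = TRUE`) but are excluded from the normative-deviation family
#' (`normative_eligible = FALSE`), which therefore contains 14 SV metrics.
#'
#' @return data.frame with columns `metric`, `family` (CT/SA/SV/GLOBAL),
#'   `hemisphere` (L/R/both), `region`, `normative_eligible`, `mega`.
#' @export
#' @examples
#' m <- region_manifest()
#' table(m$family)
region_manifest <- function() {
  hemi <- c(L = "lh", R = "rh")
  rows <- list()
  for (h in names(hemi)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0("ct_", hemi[[h]], "_", dk_regions),
      family = "CT", hemisphere = h, region = dk_regions,
      normative_eligible = TRUE, mega = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0("sa_", hemi[[h]], "_", dk_regions),
      family = "SA", hemisphere = h, region = dk_regions,
      normative_eligible = TRUE, mega = TRUE)
    sv <- c(sv_structures, "lateralventricle")
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0("sv_", hemi[[h]], "_", sv),
      family = "SV", hemisphere = h, region = sv,
      normative_eligible = sv != "lateralventricle", mega = TRUE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    metric = c("meanct_lh", "meanct_rh", "totalsa", "icv"),
    family = "GLOBAL", hemisphere = c("L", "R", "both", "both"),
    region = c("meanct", "meanct", "totalsa", "icv"),
    normative_eligible = FALSE, mega = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metric names for given families
#'
#' @param manifest a region manifest.
#' @param families character vector of families to keep (default all).
#' @param normative_only keep only normative-eligible metrics.
#' @param mega_only keep only metrics entering group comparisons and
#'   classification (drops GLOBAL).
#' @return character vector of metric names.
#' @export
metric_names <- function(manifest, families = NULL, normative_only = FALSE,
                         mega_only = FALSE) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(families)) keep <- keep & manifest$family %in% families
  if (normative_only) keep <- keep & manifest$normative_eligible
  if (mega_only) keep <- keep & manifest$mega
  manifest$metric[keep]
}

# Global covariate used by the normative model for a metric family.
global_covariate_for <- function(family) {
  switch(family, CT = "meanct", SA = "totalsa", SV = "icv",
         stop("no global covariate for family ", family))
}

#' Percentage helper
#'
#' `proportion_pct(count, n)` returns `100 * count / n`; used for all
#' reported percentages (deviation frequencies, sample descriptives).
#'
#' @param count numerator count.
#' @param n denominator count.
#' @param digits optional rounding digits.
#' @return numeric percentage.
#' @export
#' @examples
#' proportion_pct(12, 449, digits = 1)  # 2.7
proportion_pct <- function(count, n, digits = NULL) {
  stopifnot(all(n > 0), all(count >= 0), all(count <= n))
  p <- 100 * count / n
  if (!is.null(digits)) p <- round(p, digits)
  p
}
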