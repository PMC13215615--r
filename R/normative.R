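#' Fit a normative model on a healthy reference sample
#'
#' Per normative-eligible metric (68 CT, 68 SA, 14 SV), a least-squares
#' regression of the metric on a cubic B-spline of age plus the family's
#' global covariate: mean CT (average of the hemispheric means) for CT
#' metrics, total SA for SA metrics, ICV for SV metrics. The homoscedastic
#' residual SD is stored, so z-scoring the fitting sample gives mean 0 and
#' SD close to 1 per metric. The reference emulates a female-only healthy
#' sample; any non-HC row is an error.
#'
#' @param reference healthy-only `morpho_table`, n >= 500.
#' @return a `normative_model`.
#' @export
fit_normative <- function(reference) {
  if (nrow(reference) < 500) stop("reference too small (n >= 500 required)")
  if (any(reference$group != "HC"))
    stop("reference must contain healthy participants only")
  man <- table_manifest(reference)
  metrics <- intersect(metric_names(man, normative_only = TRUE),
                       names(reference))
  def <- spline_def(reference$age)
  B <- spline_eval(def, reference$age)
  globals <- list(
    CT = (reference$meanct_lh + reference$meanct_rh) / 2,
    SA = reference$totalsa,
    SV = reference$icv)
  fams <- man$family[match(metrics, man$metric)]
  coefs <- list()
  sigma <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  for (k in seq_along(metrics)) {
    v <- metrics[k]
    y <- reference[[v]]
    ok <- !is.na(y)
    X <- cbind(1, B[ok, , drop = FALSE], global = globals[[fams[k]]][ok])
    fit <- stats::lm.fit(X, y[ok])
    s <- sqrt(sum(fit$residuals^2) / (sum(ok) - fit$rank))
    if (!is.finite(s) || s < 1e-7 * stats::sd(y[ok]))
      stop("degenerate residual SD for metric ", v,
           " (metric perfectly predicted by covariates)")
    coefs[[v]] <- fit$coefficients
    sigma[v] <- s
  }
  structure(list(metrics = metrics, families = fams, coefs = coefs,
                 sigma = sigma, spline = def,
                 age_range = range(reference$age), n_fit = nrow(reference)),
            class = "normative_model")
}

#' Normative z-scores and deviation status
#'
#' `z = (observed - predicted) / residual SD` per participant and metric;
#' status is infranormal if z < -1.96, supranormal if z > 1.96 (strict
#' inequalities), normal otherwise. Missing metrics give missing z. Ages
#' outside the reference fitting range are still scored (the spline is
#' clamped at the boundary) but flagged in the `extrapolated` column.
#'
#' @param model a `normative_model`.
#' @param table a `morpho_table` (typically harmonized clinical data).
#' @return a `deviation_table`: data.frame with participant covariates,
#'   an `extrapolated` flag and one z column per metric.
#' @export
zscore <- function(model, table) {
  B <- spline_eval(model$spline, table$age)
  globals <- list(
    CT = (table$meanct_lh + table$meanct_rh) / 2,
    SA = table$totalsa,
    SV = table$icv)
  out <- data.frame(participant_id = table$participant_id,
                    site = table$site, group = table$group,
                    subtype = table$subtype, age = table$age,
                    extrapolated = table$age < model$age_range[1] |
                      table$age > model$age_range[2])
  for (k in seq_along(model$metrics)) {
    v <- model$metrics[k]
    if (!v %in% names(table)) next
    pred <- as.vector(cbind(1, B, globals[[model$families[k]]]) %*%
                        model$coefs[[v]])
    out[[v]] <- (table[[v]] - pred) / model$sigma[v]
  }
  attr(out, "metrics") <- intersect(model$metrics, names(out))
  attr(out, "families") <- model$families[model$metrics %in% names(out)]
  class(out) <- c("deviation_table", "data.frame")
  out
}

#' Deviation status from a z-score
#' @param z numeric z-scores.
#' @param threshold extreme threshold (default 1.96).
#' @return character: `"infranormal"`, `"normal"`, `"supranormal"` (NA for
#'   missing z).
#' @export
deviation_status <- function(z, threshold = 1.96) {
  ifelse(is.na(z), NA_character_,
         ifelse(z < -threshold, "infranormal",
                ifelse(z > threshold, "supranormal", "normal")))
}

#' @export
`[.deviation_table` <- function(x, ...) {
  mets <- attr(x, "metrics")
  fams <- attr(x, "families")
  out <- NextMethod()
  if (is.data.frame(out)) {
    keep <- mets %in% names(out)
    attr(out, "metrics") <- mets[keep]
    attr(out, "families") <- fams[keep]
    class(out) <- unique(c("deviation_table", class(out)))
  }
  out
}

dev_metrics <- function(dev) attr(dev, "metrics")
dev_families <- function(dev) attr(dev, "families")

#' Exact one-sided binomial exceedance test
#'
#' Upper-tail probability `P(X >= count | n, p0)` of observing at least
#' `count` extreme deviations among `n` tested when the per-tail normative
#' rate is `p0` (2.5 percent by default).
#'
#' @param count observed extreme count.
#' @param n number tested.
#' @param p0 null per-tail rate.
#' @return p-value (1 when `count` is 0).
#' @export
exceedance_test <- function(count, n, p0 = 0.025) {
  stopifnot(count >= 0, count <= n, n >= 0)
  if (n == 0) return(NA_real_)
  stats::pbinom(count - 1, n, p0, lower.tail = FALSE)
}

#' Summarize extreme-deviation frequencies
#'
#' Per metric and tail (infranormal / supranormal): extreme count, number
#' tested, percentage, exact binomial exceedance p against the normative
#' per-tail rate, Benjamini-Hochberg q within family-by-tail, and a
#' significance flag (q < alpha and percentage above the normative rate).
#' The per-family-by-tail `threshold` is the smallest percentage among
#' significant metrics (the detectability threshold reported alongside
#' deviation maps).
#'
#' @param dev a `deviation_table`.
#' @param p0 normative per-tail rate (default 0.025).
#' @param alpha FDR level.
#' @return list with `by_metric` (data.frame) and `thresholds`
#'   (family x tail minimum significant percentage, NA when none).
#' @export
summarize_deviations <- function(dev, p0 = 0.025, alpha = 0.05) {
  if (!nrow(dev)) stop("empty deviation table")
  metrics <- dev_metrics(dev)
  fams <- dev_families(dev)
  rows <- list()
  for (k in seq_along(metrics)) {
    z <- dev[[metrics[k]]]
    n <- sum(!is.na(z))
    for (tail in c("infranormal", "supranormal")) {
      cnt <- if (n == 0) 0L else
        sum(if (tail == "infranormal") z < -1.96 else z > 1.96, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metrics[k], family = fams[k], tail = tail,
        count = cnt, n = n,
        pct = if (n > 0) proportion_pct(cnt, n) else NA_real_,
        p = if (n > 0) exceedance_test(cnt, n, p0) else NA_real_)
    }
  }
  bm <- do.call(rbind, rows)
  bm$q <- NA_real_
  for (f in unique(bm$family)) for (tl in c("infranormal", "supranormal")) {
    sel <- bm$family == f & bm$tail == tl & !is.na(bm$p)
    if (any(sel)) bm$q[sel] <- bh_fdr(bm$p[sel])$q
  }
  bm$significant <- !is.na(bm$q) & bm$q < alpha & bm$pct > 100 * p0
  thr <- do.call(rbind, lapply(split(bm, list(bm$family, bm$tail)),
                               function(r) {
    data.frame(family = r$family[1], tail = r$tail[1],
               n_significant = sum(r$significant),
               threshold = if (any(r$significant))
                 min(r$pct[r$significant]) else NA_real_)
  }))
  rownames(thr) <- NULL
  list(by_metric = bm, thresholds = thr, p0 = p0, alpha = alpha)
}

#' Compare extreme-deviation proportions between subtypes
#'
#' Pooled two-proportion z-test (no continuity correction) per metric and
#' tail, with Benjamini-Hochberg FDR across all metric-by-tail tests as a
#' single family. Metrics with zero tested participants in either group
#' are skipped.
#'
#' @param dev1,dev2 `deviation_table`s for the two groups (e.g., AN-R and
#'   AN-BP).
#' @return data.frame with per-metric counts, proportions, z, p, q and
#'   significance flags.
#' @export
compare_subtype_proportions <- function(dev1, dev2, alpha = 0.05) {
  if (!nrow(dev1) || !nrow(dev2)) stop("both deviation tables must be non-empty")
  metrics <- intersect(dev_metrics(dev1), dev_metrics(dev2))
  fams <- dev_families(dev1)[match(metrics, dev_metrics(dev1))]
  rows <- list()
  for (k in seq_along(metrics)) {
    z1 <- dev1[[metrics[k]]]
    z2 <- dev2[[metrics[k]]]
    n1 <- sum(!is.na(z1))
    n2 <- sum(!is.na(z2))
    if (n1 == 0 || n2 == 0) next
    for (tail in c("infranormal", "supranormal")) {
      c1 <- sum(if (tail == "infranormal") z1 < -1.96 else z1 > 1.96,
                na.rm = TRUE)
      c2 <- sum(if (tail == "infranormal") z2 < -1.96 else z2 > 1.96,
                na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metrics[k], family = fams[k], tail = tail,
        count1 = c1, n1 = n1, count2 = c2, n2 = n2,
        z = two_proportion_z(c1, n1, c2, n2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no metric testable in both groups")
  out$p <- 2 * stats::pnorm(-abs(out$z))
  # one FDR family across all metric-by-tail tests
  out$q <- bh_fdr(out$p)$q
  out$significant <- out$q < alpha
  out
}

#' Pooled two-proportion z statistic
#'
#' `z = (p1 - p2) / sqrt(p * (1 - p) * (1/n1 + 1/n2))` with `p` the pooled
#' proportion; 0 when the proportions are equal (including both zero).
#'
#' @param c1,n1,c2,n2 counts and totals.
#' @return z statistic.
#' @export
two_proportion_z <- function(c1, n1, c2, n2) {
  p1 <- c1 / n1
  p2 <- c2 / n2
  pp <- (c1 + c2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  ifelse(se == 0, 0, (p1 - p2) / se)
}

#' Heterogeneity indices with bootstrap significance
#'
#' Per family, the index is the mean over metrics of the SD of z-scores
#' across participants. Significance against the reference is assessed by
#' resampling participants with replacement from the reference deviation
#' table, size-matched to the clinical group; `p` is the fraction of
#' bootstrap indices at least as large as the observed one.
#'
#' @param dev clinical `deviation_table`.
#' @param reference_dev held-out reference `deviation_table`.
#' @param n_boot bootstrap draws (>= 200).
#' @param seed integer seed.
#' @return data.frame per family: `index`, `index_ref`, `p_boot`.
#' @export
heterogeneity <- function(dev, reference_dev, n_boot = 1000, seed = 1) {
  if (n_boot < 200) stop("n_boot must be >= 200")
  if (nrow(dev) < 2) stop("need at least 2 participants for an SD")
  fam_index <- function(d, rows = seq_len(nrow(d))) {
    mets <- dev_metrics(d)
    fams <- dev_families(d)
    sapply(split(mets, fams), function(ms) {
      if (length(ms) < 2) stop("family with <2 metrics")
      mean(sapply(ms, function(v) stats::sd(d[[v]][rows], na.rm = TRUE)))
    })
  }
  obs <- fam_index(dev)
  ref <- fam_index(reference_dev)
  boot <- with_seed(child_seed(seed, "heterogeneity_boot"), {
    replicate(n_boot, fam_index(
      reference_dev, sample.int(nrow(reference_dev), nrow(dev),
                                replace = TRUE)))
  })
  p <- sapply(names(obs), function(f) mean(boot[f, ] >= obs[[f]]))
  data.frame(family = names(obs), index = unname(obs),
             index_ref = unname(ref[names(obs)]), p_boot = unname(p))
}
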