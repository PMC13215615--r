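#' Covariate policy for a group contrast
#'
#' Pure function of the contrast and metric family: mean-centred age and its
#' square always; BMI only for the AN-R vs AN-BP contrast; ICV only for SA
#' and SV metrics.
#'
#' @param grouping `"AN_vs_HC"` or `"ANR_vs_ANBP"`.
#' @param family metric family (`"CT"`, `"SA"`, `"SV"`, `"GLOBAL"`).
#' @return character vector of covariate column names (with `"age2"` for
#'   the quadratic term).
#' @export
contrast_covariates <- function(grouping = c("AN_vs_HC", "ANR_vs_ANBP"),
                                family) {
  grouping <- match.arg(grouping)
  cov <- c("age", "age2")
  if (grouping == "ANR_vs_ANBP") cov <- c(cov, "bmi")
  if (family %in% c("SA", "SV")) cov <- c(cov, "icv")
  cov
}

# Binary contrast labels: first-named group is coded 1 so the group
# coefficient (and d) is group1 minus group2.
contrast_labels <- function(table, grouping) {
  if (grouping == "AN_vs_HC") {
    list(rows = seq_len(nrow(table)),
         y = as.integer(table$group == "AN"),
         groups = c("AN", "HC"))
  } else {
    keep <- which(table$group == "AN" &
                    table$subtype %in% c("AN-R", "AN-BP"))
    list(rows = keep,
         y = as.integer(table$subtype[keep] == "AN-R"),
         groups = c("AN-R", "AN-BP"))
  }
}

#' Per-metric general linear model with covariate-adjusted Cohen's d
#'
#' OLS fit of `metric ~ group + covariates` on complete cases; the
#' t-statistic of the group indicator is converted to Cohen's d via
#' `d = t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))` with `df` the residual
#' degrees of freedom, and a normal-approximation 95 percent CI uses
#' `SE(d) = sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * df))`.
#'
#' @param table a harmonized `morpho_table`.
#' @param metric metric column name.
#' @param grouping contrast, as in [contrast_covariates()].
#' @param min_per_group minimum complete cases per group (default 10).
#' @return one-row data.frame (`metric`, `n1`, `n2`, `t`, `d`, `d_lo`,
#'   `d_hi`, `p`), or NULL (with a message) when cases are insufficient.
#' @export
fit_glm_metric <- function(table, metric, grouping = "AN_vs_HC",
                           min_per_group = 10) {
  man <- table_manifest(table)
  fam <- man$family[man$metric == metric]
  if (!length(fam)) stop("unknown metric ", metric)
  lab <- contrast_labels(table, grouping)
  df0 <- as.data.frame(table)[lab$rows, , drop = FALSE]
  y <- df0[[metric]]
  ok <- !is.na(y)
  g <- lab$y[ok]
  n1 <- sum(g == 1)
  n2 <- sum(g == 0)
  if (n1 < min_per_group || n2 < min_per_group) {
    message("metric ", metric, " skipped: insufficient complete cases (",
            n1, "/", n2, ")")
    return(NULL)
  }
  if (stats::sd(y[ok]) == 0) stop("constant metric ", metric)
  covs <- contrast_covariates(grouping, fam)
  age_c <- df0$age[ok] - mean(df0$age[ok])
  Z <- cbind(group = g, age = age_c, age2 = age_c^2)
  if ("bmi" %in% covs) Z <- cbind(Z, bmi = df0$bmi[ok])
  if ("icv" %in% covs) Z <- cbind(Z, icv = df0$icv[ok])
  Xf <- cbind(1, Z)
  fit <- stats::lm.fit(Xf, y[ok])
  dfres <- length(fit$residuals) - fit$rank
  s2 <- sum(fit$residuals^2) / dfres
  XtXinv <- solve(crossprod(Xf))
  se <- sqrt(s2 * XtXinv[2, 2])
  tval <- fit$coefficients[2] / se
  d <- d_from_t(tval, n1, n2, dfres)
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * dfres))
  p <- 2 * stats::pt(-abs(tval), dfres)
  data.frame(metric = metric, family = fam, n1 = n1, n2 = n2,
             t = unname(tval), d = unname(d),
             d_lo = unname(d - 1.96 * se_d), d_hi = unname(d + 1.96 * se_d),
             p = unname(p))
}

#' Cohen's d from a covariate-adjusted t statistic
#'
#' @param t t-statistic of the group coefficient.
#' @param n1,n2 group sizes.
#' @param df residual degrees of freedom.
#' @return Cohen's d.
#' @export
#' @examples
#' d_from_t(2, 50, 50, 96)  # about 0.408
d_from_t <- function(t, n1, n2, df) {
  t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min over j >= i of m * p_(j) / j`, mapped back to input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha rejection level (default 0.05).
#' @return list with `q` (adjusted values, capped at 1) and `reject`
#'   (`q <= alpha`); empty inputs give empty outputs.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(q = numeric(0), reject = logical(0)))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(m * pvalues[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q = q, reject = q <= alpha)
}

#' Run the mega-analysis over all regional metrics
#'
#' Fits [fit_glm_metric()] for every mega-analysis metric (68 CT, 68 SA,
#' 16 SV), applies Benjamini-Hochberg FDR within metric family (or pooled
#' across families), and summarizes each family: counts of significantly
#' lower/higher metrics and mean (SD) of d over significant metrics, both
#' overall and restricted to the significantly lower ones (the quantity
#' conventionally reported for deficit profiles).
#'
#' @param table a harmonized `morpho_table`.
#' @param grouping contrast.
#' @param per_family apply FDR within family (default) or pooled.
#' @param alpha FDR level.
#' @return list with `results` (per-metric data.frame incl. `q` and
#'   `significant`, meaning q < alpha) and `family_summary`.
#' @export
run_mega <- function(table, grouping = "AN_vs_HC", per_family = TRUE,
                     alpha = 0.05) {
  man <- table_manifest(table)
  metrics <- intersect(metric_names(man, mega_only = TRUE), names(table))
  res <- do.call(rbind, lapply(metrics, function(mt)
    fit_glm_metric(table, mt, grouping)))
  if (is.null(res) || !nrow(res)) stop("no metric could be tested")
  if (per_family) {
    res$q <- NA_real_
    for (f in unique(res$family))
      res$q[res$family == f] <- bh_fdr(res$p[res$family == f])$q
  } else {
    res$q <- bh_fdr(res$p)$q
  }
  res$significant <- res$q < alpha
  fam_sum <- do.call(rbind, lapply(split(res, res$family), function(r) {
    sig <- r[r$significant, ]
    lo <- sig[sig$d < 0, ]
    data.frame(family = r$family[1], n_metrics = nrow(r),
               n_sig_lower = nrow(lo), n_sig_higher = sum(sig$d > 0),
               mean_d_sig = if (nrow(sig)) mean(sig$d) else NA_real_,
               sd_d_sig = if (nrow(sig) > 1) stats::sd(sig$d) else NA_real_,
               # the printed family effect sizes average over the
               # significantly *lower* metrics only
               mean_d_sig_lower = if (nrow(lo)) mean(lo$d) else NA_real_,
               sd_d_sig_lower = if (nrow(lo) > 1) stats::sd(lo$d)
                                else NA_real_)
  }))
  rownames(fam_sum) <- NULL
  list(results = res, family_summary = fam_sum, grouping = grouping,
       alpha = alpha, per_family = per_family)
}
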