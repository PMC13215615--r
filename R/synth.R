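#' Default per-site layout of the synthetic consortium
#'
#' Eleven sites with uneven case/control splits whose pooled totals are
#' 570 AN (417 restricting, 135 binge/purge, 18 without subtype information
#' at the last site) and 739 HC. Site-level age means vary between roughly
#' 16 and 26 years; additive site offsets (in units of the metric residual
#' SD) and multiplicative residual-scale factors emulate scanner and
#' protocol differences.
#'
#' @return data.frame with one row per site.
#' @export
default_site_table <- function() {
  data.frame(
    site = sprintf("site%02d", 1:11),
    n_an_r   = c(60, 53, 49, 45, 42, 38, 34, 34, 32, 30, 0),
    n_an_bp  = c(20, 17, 16, 15, 13, 12, 11, 11, 10, 10, 0),
    n_an_nos = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 18),
    n_hc     = c(100, 90, 85, 80, 70, 65, 60, 60, 55, 50, 24),
    age_mean = c(16.5, 18, 19, 20, 21, 22, 23, 24, 25, 26, 21),
    age_sd   = c(2.5, 3, 3.5, 4, 4, 4.5, 4.5, 5, 5, 5, 4),
    shift    = c(-0.6, -0.45, -0.3, -0.15, 0, 0.1, 0.2, 0.3, 0.4, 0.5, 0),
    scale    = c(0.85, 0.9, 0.95, 1, 1, 1, 1.05, 1.05, 1.1, 1.15, 1))
}

#' Default per-metric case-control effect sizes
#'
#' Cohen's d (AN minus HC) per metric, drawn once from family-level
#' distributions and affinely adjusted so that the realized family mean and
#' SD are exact: CT -0.54 (0.22), SA -0.23 (0.07), SV structures -0.37
#' (0.13). Two cortical-thickness exceptions are set positive (left temporal
#' pole +0.15, right entorhinal +0.13) and the lateral ventricles are
#' enlarged (+0.30). The draw uses a fixed internal seed so the profile is a
#' constant of the package, independent of the user's cohort seed.
#'
#' @param manifest region manifest.
#' @return named numeric vector of d values over the mega-analysis metrics.
#' @export
default_effect_sizes <- function(manifest = region_manifest()) {
  draw_family <- function(nms, mean, sd) {
    x <- stats::rnorm(length(nms))
    x <- (x - mean(x)) / stats::sd(x) * sd + mean
    names(x) <- nms
    x
  }
  with_seed(20260520, {
    ct <- metric_names(manifest, "CT")
    ct_exc <- c(ct_lh_temporalpole = 0.15, ct_rh_entorhinal = 0.13)
    ct_reg <- setdiff(ct, names(ct_exc))
    d_ct <- c(draw_family(ct_reg, -0.54, 0.22), ct_exc)[ct]
    sa <- metric_names(manifest, "SA")
    d_sa <- draw_family(sa, -0.23, 0.07)
    sv <- metric_names(manifest, "SV")
    vent <- sv[grepl("lateralventricle", sv)]
    d_sv <- c(draw_family(setdiff(sv, vent), -0.37, 0.13),
              stats::setNames(rep(0.30, length(vent)), vent))[sv]
    c(d_ct, d_sa, d_sv)
  })
}

# Per-metric location and residual-SD parameters of the generative model,
# a deterministic function of the manifest (typical FreeSurfer magnitudes).
metric_params <- function(manifest) {
  m <- manifest[manifest$family != "GLOBAL", ]
  mu <- sd <- numeric(nrow(m))
  idx <- stats::ave(seq_len(nrow(m)), m$family, FUN = seq_along)
  ct <- m$family == "CT"
  mu[ct] <- 2.5 + 0.012 * (idx[ct] %% 7)
  sd[ct] <- 0.15
  sa <- m$family == "SA"
  mu[sa] <- 2000 + 45 * (idx[sa] %% 11)
  sd[sa] <- 250
  sv <- m$family == "SV"
  base <- c(thalamus = 7000, caudate = 3700, putamen = 5000, pallidum = 1700,
            hippocampus = 4000, amygdala = 1600, accumbens = 600,
            lateralventricle = 7000)
  mu[sv] <- base[m$region[sv]]
  sd[sv] <- ifelse(m$region[sv] == "lateralventricle", 0.45, 0.12) * mu[sv]
  data.frame(metric = m$metric, family = m$family, mu = mu, sigma = sd)
}

#' Cohort configuration
#'
#' Describes the synthetic multi-site case-control cohort: per-site group
#' and subtype counts, per-site age distributions and site location/scale
#' effects, per-group BMI distributions, per-metric Cohen's d for the AN-HC
#' contrast, residual-SD inflation in AN, and a missingness rate.
#'
#' Defaults reproduce the consortium layout: 570 AN (417 AN-R / 135 AN-BP /
#' 18 unlabelled) and 739 HC over 11 sites; AN BMI 15.49 (1.54) kg/m2 versus
#' HC 21.33 (2.20); AN-BP on average older and heavier than AN-R (a
#' demographic difference with zero true brain effect, so subtype analyses
#' are null by construction); residual-SD inflation 1.3 in AN.
#'
#' @param sites data.frame as [default_site_table()].
#' @param bmi_params named list of c(mean, sd) for `AN_R`, `AN_BP`, `AN_NOS`,
#'   `HC`.
#' @param effect_sizes named per-metric Cohen's d (AN minus HC), in units of
#'   the base residual SD.
#' @param an_sd_inflation ratio (>= 1) of AN to HC residual SD.
#' @param subtype_age_shift additive age shift (years) for AN-BP.
#' @param icv_loading correlation-inducing loading of standardized ICV on SA
#'   and SV metrics (in residual-SD units); 0.6 gives marginal r of about
#'   0.5.
#' @param missing_rate fraction of regional cells masked at random, in
#'   [0, 0.1].
#' @param seed integer seed.
#' @param manifest region manifest.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(sites = default_site_table(),
                          bmi_params = list(AN_R = c(15.27, 1.50),
                                            AN_BP = c(16.20, 1.50),
                                            AN_NOS = c(15.49, 1.54),
                                            HC = c(21.33, 2.20)),
                          effect_sizes = NULL,
                          an_sd_inflation = 1.3,
                          subtype_age_shift = 2.5,
                          icv_loading = 0.6,
                          missing_rate = 0,
                          seed = 1,
                          manifest = region_manifest()) {
  stopifnot(is.data.frame(sites),
            all(c("site", "n_an_r", "n_an_bp", "n_an_nos", "n_hc",
                  "age_mean", "age_sd", "shift", "scale") %in% names(sites)))
  counts <- sites[, c("n_an_r", "n_an_bp", "n_an_nos", "n_hc")]
  if (any(counts < 0)) stop("group counts must be >= 0")
  if (any(sites$scale <= 0)) stop("site_scale must be > 0")
  if (an_sd_inflation < 1) stop("an_sd_inflation must be >= 1")
  if (missing_rate < 0 || missing_rate > 0.1)
    stop("missing_rate must be in [0, 0.1]")
  if (is.null(effect_sizes)) effect_sizes <- default_effect_sizes(manifest)
  mm <- metric_names(manifest, mega_only = TRUE)
  if (!all(mm %in% names(effect_sizes)))
    stop("effect_sizes must name every mega-analysis metric")
  cfg <- list(sites = sites, bmi_params = bmi_params,
              effect_sizes = effect_sizes[mm],
              an_sd_inflation = an_sd_inflation,
              subtype_age_shift = subtype_age_shift,
              icv_loading = icv_loading,
              missing_rate = missing_rate, seed = as.integer(seed),
              manifest = manifest)
  class(cfg) <- "cohort_config"
  cfg
}

#' Compact two-site configuration
#'
#' Convenience layout for simulation studies at a chosen total sample size,
#' keeping the default case/control ratio (570:739), subtype ratio
#' (417:135), and default effect sizes.
#'
#' @param n total participants.
#' @param n_sites number of sites (participants split evenly).
#' @param seed integer seed.
#' @param ... passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
small_cohort_config <- function(n = 400, n_sites = 2, seed = 1, ...) {
  per <- floor(n / n_sites)
  n_an <- round(per * 570 / 1309)
  n_r <- round(n_an * 417 / 552)
  base <- default_site_table()[seq_len(n_sites), ]
  base$n_an_r <- n_r
  base$n_an_bp <- n_an - n_r
  base$n_an_nos <- 0
  base$n_hc <- per - n_an
  base$age_mean <- seq(18, 24, length.out = n_sites)
  base$age_sd <- 4
  base$shift <- seq(-0.3, 0.3, length.out = n_sites)
  base$scale <- seq(0.9, 1.1, length.out = n_sites)
  cohort_config(sites = base, seed = seed, ...)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Generate a synthetic multi-site cohort
#'
#' Per-metric generative model, with sigma the base residual SD of the
#' metric:
#' `y = mu + f(age) + d * sigma * 1(AN) + shift_site * sigma +
#'  lambda * sigma * z(ICV) + scale_site * inflation^1(AN) * sigma * eps`,
#' where `f(age)` is a mild piecewise-linear decline after age 8 for CT
#' (flat for SA/SV), `z(ICV)` is the standardized intracranial volume
#' (entering SA and SV metrics only), and `eps` is standard normal.
#' Global metrics (mean CT per hemisphere, total SA) are derived from the
#' regional ones. Deterministic given the config (which carries the seed).
#'
#' Note that with `an_sd_inflation > 1` the population pooled-SD Cohen's d
#' is attenuated relative to the injected `d` by
#' `sqrt(f * inflation^2 + 1 - f)` with `f` the AN fraction (about 1.14 at
#' the defaults).
#'
#' @param config a [cohort_config()].
#' @return a `morpho_table`.
#' @export
#' @examples
#' tab <- generate_cohort(small_cohort_config(n = 120, seed = 7))
#' table(tab$group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  s <- config$sites
  n_an <- s$n_an_r + s$n_an_bp + s$n_an_nos
  n_tot <- sum(n_an) + sum(s$n_hc)
  rows <- with_seed(child_seed(config$seed, "cohort"), {
    site <- group <- subtype <- character(0)
    age <- numeric(0)
    site_idx <- integer(0)
    for (i in seq_len(nrow(s))) {
      ni <- n_an[i] + s$n_hc[i]
      if (ni == 0) next
      st <- c(rep("AN-R", s$n_an_r[i]), rep("AN-BP", s$n_an_bp[i]),
              rep("none", s$n_an_nos[i] + s$n_hc[i]))
      gr <- c(rep("AN", n_an[i]), rep("HC", s$n_hc[i]))
      a <- rnorm_trunc(ni, s$age_mean[i], s$age_sd[i], 10) +
        config$subtype_age_shift * (st == "AN-BP")
      site <- c(site, rep(s$site[i], ni))
      site_idx <- c(site_idx, rep(i, ni))
      group <- c(group, gr)
      subtype <- c(subtype, st)
      age <- c(age, a)
    }
    bp <- config$bmi_params
    key <- ifelse(group == "HC", "HC",
                  ifelse(subtype == "AN-R", "AN_R",
                         ifelse(subtype == "AN-BP", "AN_BP", "AN_NOS")))
    bmi <- numeric(length(group))
    for (k in unique(key)) {
      idx <- key == k
      bmi[idx] <- rnorm_trunc(sum(idx), bp[[k]][1], bp[[k]][2], 11)
    }
    icv <- rnorm_trunc(length(group), 1.45e6, 1.4e5, 9e5)
    list(site = site, site_idx = site_idx, group = group, subtype = subtype,
         age = age, bmi = bmi, icv = icv)
  })
  d <- config$effect_sizes
  d <- d[metric_names(config$manifest, mega_only = TRUE)]
  tab <- with_seed(child_seed(config$seed, "metrics"), {
    synth_metrics(rows, d, config)
  })
  if (config$missing_rate > 0) {
    tab <- apply_missingness(tab, config$missing_rate,
                             child_seed(config$seed, "missing"))
  }
  tab
}

# Shared metric synthesis for cohorts and the normative reference.
synth_metrics <- function(rows, d, config) {
  man <- config$manifest
  pars <- metric_params(man)
  pars <- pars[match(names(d), pars$metric), ]
  n <- length(rows$group)
  m <- length(d)
  is_an <- rows$group == "AN"
  shift <- config$sites$shift[rows$site_idx]
  scale <- config$sites$scale[rows$site_idx]
  infl <- ifelse(is_an, config$an_sd_inflation, 1)
  icv_z <- (rows$icv - 1.45e6) / 1.4e5
  age_dec <- pmax(rows$age - 8, 0)
  eps <- matrix(stats::rnorm(n * m), n, m)
  Y <- matrix(0, n, m, dimnames = list(NULL, pars$metric))
  for (j in seq_len(m)) {
    sig <- pars$sigma[j]
    f_age <- if (pars$family[j] == "CT") -0.02 * sig * age_dec else 0
    icv_term <- if (pars$family[j] %in% c("SA", "SV"))
      config$icv_loading * sig * icv_z else 0
    Y[, j] <- pars$mu[j] + f_age + d[j] * sig * is_an + shift * sig +
      icv_term + scale * infl * sig * eps[, j]
  }
  df <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    site = rows$site, group = rows$group, subtype = rows$subtype,
    age = rows$age, bmi = rows$bmi, icv = rows$icv)
  df <- cbind(df, as.data.frame(Y))
  ct_lh <- metric_names(man, "CT")[grepl("_lh_", metric_names(man, "CT"))]
  ct_rh <- metric_names(man, "CT")[grepl("_rh_", metric_names(man, "CT"))]
  df$meanct_lh <- rowMeans(Y[, ct_lh, drop = FALSE])
  df$meanct_rh <- rowMeans(Y[, ct_rh, drop = FALSE])
  df$totalsa <- rowSums(Y[, metric_names(man, "SA"), drop = FALSE])
  as_morpho_table(df, man)
}

#' Generate a healthy normative reference sample
#'
#' Single-group (HC) sample spanning ages 5-90 under the same metric model
#' as [generate_cohort()] with no group effect, no site effects and unit
#' residual scale; used exclusively to fit the normative model.
#'
#' @param n number of participants (>= 500).
#' @param seed integer seed.
#' @param manifest region manifest.
#' @return a `morpho_table` with a single site `"reference"`.
#' @export
generate_reference <- function(n, seed = 1, manifest = region_manifest()) {
  if (n < 500) stop("reference sample too small to fit normative curves")
  cfg <- cohort_config(seed = seed, manifest = manifest)
  rows <- with_seed(child_seed(seed, "reference"), {
    age <- pmin(pmax(stats::rgamma(n, shape = 6, scale = 4) + 5, 5), 90)
    list(site = rep("reference", n), site_idx = rep(5L, n),
         group = rep("HC", n), subtype = rep("none", n), age = age,
         bmi = rnorm_trunc(n, 21.33, 2.20, 11),
         icv = rnorm_trunc(n, 1.45e6, 1.4e5, 9e5))
  })
  d0 <- cfg$effect_sizes * 0
  cfg$sites$shift[] <- 0
  cfg$sites$scale[] <- 1
  with_seed(child_seed(seed, "reference_metrics"),
            synth_metrics(rows, d0, cfg))
}

#' Mask regional metric cells at random
#'
#' Emulates region-by-region removal of failed segmentations: each regional
#' (CT/SA/SV) cell is independently set to `NA` with probability `rate`.
#' Covariates and derived global metrics are never masked.
#'
#' @param table a `morpho_table`.
#' @param rate masking probability in [0, 0.1].
#' @param seed integer seed.
#' @return the masked table.
#' @export
apply_missingness <- function(table, rate, seed = 1) {
  if (rate < 0 || rate > 0.1) stop("rate must be in [0, 0.1]")
  if (rate == 0) return(table)
  man <- table_manifest(table)
  cols <- intersect(metric_names(man, mega_only = TRUE), names(table))
  with_seed(child_seed(seed, "mask"), {
    for (cl in cols) {
      mask <- stats::runif(nrow(table)) < rate
      table[[cl]][mask] <- NA_real_
    }
  })
  table
}
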