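#' Covariate specification for harmonization
#'
#' Declares which biological effects the harmonization must preserve:
#' covariates modelled with a spline basis (nonlinear age by default),
#' linear covariates (BMI, ICV), and categorical effects (diagnosis or
#' subtype). Site must never appear among the retained effects.
#'
#' @param smooth_terms covariates modelled with a cubic B-spline basis.
#' @param linear_terms covariates entering linearly.
#' @param retained_factors categorical columns whose effects are preserved.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(smooth_terms = "age",
                           linear_terms = character(0),
                           retained_factors = character(0)) {
  all_terms <- c(smooth_terms, linear_terms, retained_factors)
  if (anyDuplicated(all_terms)) stop("a covariate appears twice in the spec")
  if ("site" %in% retained_factors)
    stop("site cannot be a retained factor")
  structure(list(smooth_terms = smooth_terms, linear_terms = linear_terms,
                 retained_factors = retained_factors),
            class = "covariate_spec")
}

# Cubic B-spline basis with 5 interior knots at quantiles of the training
# values; new data are clamped to the training boundary before evaluation.
spline_def <- function(x, n_knots = 5) {
  qs <- stats::quantile(x, probs = seq_len(n_knots) / (n_knots + 1),
                        names = FALSE)
  list(knots = unique(qs), boundary = range(x), degree = 3)
}

spline_eval <- function(def, x) {
  x <- pmin(pmax(x, def$boundary[1]), def$boundary[2])
  splines::bs(x, knots = def$knots, degree = def$degree,
              Boundary.knots = def$boundary, intercept = FALSE)
}

# Covariate design matrix (no intercept; the site block absorbs it).
build_cov_design <- function(table, spec, defs, factor_levels) {
  n <- nrow(table)
  parts <- list()
  for (v in spec$smooth_terms) {
    B <- spline_eval(defs[[v]], table[[v]])
    colnames(B) <- paste0("s(", v, ")", seq_len(ncol(B)))
    parts[[length(parts) + 1L]] <- B
  }
  for (v in spec$linear_terms) {
    parts[[length(parts) + 1L]] <-
      matrix(table[[v]], n, 1, dimnames = list(NULL, v))
  }
  for (v in spec$retained_factors) {
    lev <- factor_levels[[v]]
    f <- factor(table[[v]], levels = lev)
    if (any(is.na(f))) stop("unknown level in retained factor ", v)
    if (length(lev) > 1) {
      M <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(M) <- paste0(v, lev[-1])
      parts[[length(parts) + 1L]] <- M
    }
  }
  if (!length(parts)) return(matrix(0, n, 0))
  do.call(cbind, parts)
}

#' Fit ComBat-GAM site harmonization
#'
#' Per metric: (1) fit an OLS model with one indicator per site plus the
#' retained covariates (spline age, linear terms, factor effects);
#' (2) standardize residuals by the pooled residual SD; (3) estimate
#' per-site location/scale of the standardized data; (4) shrink the site
#' parameters via empirical Bayes (normal prior on location,
#' inverse-gamma on scale, hyperparameters by method of moments across
#' metrics, iterated conditional posterior means until the largest change
#' is below `tol`).
#'
#' Metrics with missing cells are fitted on complete cases. A site
#' contributing fewer than 3 usable values to a metric is excluded from
#' empirical-Bayes estimation for that metric (identity adjustment, with a
#' warning). Single-site input yields an identity adjustment. `eb = FALSE`
#' disables shrinkage (location/scale adjustment with the raw site
#' estimates), intended for oracle testing.
#'
#' @param table a `morpho_table`.
#' @param spec a [covariate_spec()].
#' @param metrics metric columns to harmonize (default: all manifest metrics
#'   present).
#' @param eb use empirical-Bayes shrinkage (default TRUE).
#' @param tol,max_iter EB convergence controls.
#' @return a `combat_gam` model.
#' @export
fit_combat_gam <- function(table, spec = covariate_spec(), metrics = NULL,
                           eb = TRUE, tol = 1e-6, max_iter = 100) {
  man <- table_manifest(table)
  if (is.null(metrics)) metrics <- intersect(man$metric, names(table))
  # a column serving as covariate cannot also be harmonized
  metrics <- setdiff(metrics, c(spec$smooth_terms, spec$linear_terms))
  sites <- sort(unique(table$site))
  n <- nrow(table)
  if (n == 0) stop("empty table")
  defs <- lapply(stats::setNames(spec$smooth_terms, spec$smooth_terms),
                 function(v) spline_def(table[[v]]))
  factor_levels <- lapply(
    stats::setNames(spec$retained_factors, spec$retained_factors),
    function(v) sort(unique(as.character(table[[v]]))))
  Xcov <- build_cov_design(table, spec, defs, factor_levels)
  S <- matrix(0, n, length(sites), dimnames = list(NULL, sites))
  S[cbind(seq_len(n), match(table$site, sites))] <- 1
  X <- cbind(S, Xcov)
  if (ncol(Xcov) > 0 && qr(cbind(1, Xcov))$rank < ncol(Xcov) + 1)
    stop("rank-deficient design: collinear covariate terms among ",
         paste(colnames(Xcov), collapse = ", "))
  Y <- metric_matrix(table, metrics)
  m <- length(metrics)
  p <- ncol(Xcov)
  nsite <- length(sites)
  beta_site <- matrix(NA_real_, nsite, m, dimnames = list(sites, metrics))
  beta_cov <- matrix(NA_real_, p, m, dimnames = list(colnames(Xcov), metrics))
  sigma <- alpha <- stats::setNames(rep(NA_real_, m), metrics)
  gamma_hat <- delta2_hat <- matrix(NA_real_, nsite, m,
                                    dimnames = list(sites, metrics))
  n_site_metric <- matrix(0L, nsite, m, dimnames = list(sites, metrics))
  site_f <- factor(table$site, levels = sites)
  fit_cols <- function(cols, rows) {
    present <- which(tabulate(site_f[rows], nbins = nsite) > 0)
    Xr <- X[rows, c(present, nsite + seq_len(p)), drop = FALSE]
    Yr <- Y[rows, cols, drop = FALSE]
    qrX <- qr(Xr)
    if (qrX$rank < ncol(Xr)) stop("rank-deficient design within metric fit")
    B <- qr.coef(qrX, Yr)
    res <- Yr - Xr %*% B
    ni <- tabulate(site_f[rows], nbins = nsite)[present]
    for (k in seq_along(cols)) {
      j <- cols[k]
      beta_site[present, j] <<- B[seq_along(present), k]
      if (p > 0) beta_cov[, j] <<- B[length(present) + seq_len(p), k]
      alpha[j] <<- sum(ni / sum(ni) * beta_site[present, j])
      sigma[j] <<- sqrt(mean(res[, k]^2))
      if (sigma[j] < 1e-10 * max(1, abs(alpha[j])))
        stop("degenerate residual SD for metric ", metrics[j])
      z <- (Yr[, k] -
              (if (p > 0) Xr[, length(present) + seq_len(p),
                             drop = FALSE] %*% beta_cov[, j] else 0) -
              alpha[j]) / sigma[j]
      sf <- site_f[rows]
      for (i in seq_len(nsite)) {
        zi <- z[sf == sites[i]]
        n_site_metric[i, j] <<- length(zi)
        if (length(zi) >= 3) {
          gamma_hat[i, j] <<- mean(zi)
          delta2_hat[i, j] <<- max(stats::var(zi), 1e-8)
        }
      }
    }
  }
  has_na <- colSums(is.na(Y)) > 0
  idx <- stats::setNames(seq_len(m), metrics)
  if (any(!has_na)) fit_cols(idx[!has_na], seq_len(n))
  for (j in idx[has_na]) {
    rows <- which(!is.na(Y[, j]))
    if (!length(rows)) {
      warning("metric ", metrics[j], " has no observed values; skipped")
      next
    }
    fit_cols(j, rows)
  }
  low <- which(n_site_metric > 0 & n_site_metric < 3 &
                 is.na(gamma_hat), arr.ind = TRUE)
  if (nrow(low))
    warning(sprintf(
      "%d site-by-metric cells with <3 usable values excluded from EB",
      nrow(low)))
  if (nsite == 1) {
    gamma_star <- matrix(0, 1, m, dimnames = list(sites, metrics))
    delta_star <- matrix(1, 1, m, dimnames = list(sites, metrics))
  } else if (!eb || m < 2) {
    gamma_star <- gamma_hat
    delta_star <- sqrt(delta2_hat)
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (i in seq_len(nsite)) {
      ok <- which(!is.na(gamma_hat[i, ]))
      if (length(ok) < 2) next
      g <- gamma_hat[i, ok]
      d2 <- delta2_hat[i, ok]
      g_bar <- mean(g)
      t2 <- stats::var(g)
      s2 <- stats::var(d2)
      d2m <- mean(d2)
      lambda <- if (s2 > 0) (2 * s2 + d2m^2) / s2 else 100
      theta <- if (s2 > 0) (d2m * s2 + d2m^3) / s2 else d2m * (lambda - 1)
      ni <- n_site_metric[i, ok]
      g_new <- g
      d2_new <- d2
      # sums of squares around the site mean are fixed within iteration
      for (it in seq_len(max_iter)) {
        g_old <- g_new
        d2_old <- d2_new
        g_new <- (ni * t2 * g + d2_new * g_bar) / (ni * t2 + d2_new)
        ss <- (ni - 1) * d2 + ni * (g - g_new)^2
        d2_new <- (theta + 0.5 * ss) / (ni / 2 + lambda - 1)
        d2_new <- pmax(d2_new, 1e-8)
        if (max(abs(g_new - g_old), abs(d2_new - d2_old)) < tol) break
      }
      gamma_star[i, ok] <- g_new
      delta2_star[i, ok] <- d2_new
    }
    delta_star <- sqrt(delta2_star)
  }
  # sites excluded from EB for a metric: identity adjustment there
  gamma_star[is.na(gamma_star)] <- 0
  delta_star[is.na(delta_star)] <- 1
  structure(list(metrics = metrics, sites = sites, spec = spec,
                 spline_defs = defs, factor_levels = factor_levels,
                 beta_cov = beta_cov, alpha = alpha, sigma = sigma,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 n_site_metric = n_site_metric, eb = eb),
            class = "combat_gam")
}

#' Apply a fitted harmonization model
#'
#' Transforms metric values of rows from known sites:
#' `y* = sigma * (z - gamma*_site) / delta*_site + covariate reconstruction`
#' with `z` the standardized residual under the stored covariate model.
#' No parameter depends on the rows being transformed, so the model can be
#' applied to held-out data without leakage. Unknown sites are an error
#' (leave-site-out pipelines must omit harmonization).
#'
#' @param model a `combat_gam` model.
#' @param table a `morpho_table` whose sites all appear in the model roster.
#' @return the table with harmonized metric columns.
#' @export
apply_combat_gam <- function(model, table) {
  if (nrow(table) == 0) return(table)
  bad <- setdiff(unique(table$site), model$sites)
  if (length(bad))
    stop("unknown site(s): ", paste(bad, collapse = ", "),
         " (harmonization cannot transform unseen sites)")
  Xcov <- build_cov_design(table, model$spec, model$spline_defs,
                           model$factor_levels)
  site_i <- match(table$site, model$sites)
  for (j in seq_along(model$metrics)) {
    v <- model$metrics[j]
    if (is.na(model$sigma[j])) next
    y <- table[[v]]
    obs <- !is.na(y)
    if (!any(obs)) next
    fit_cov <- if (ncol(Xcov) > 0)
      as.vector(Xcov[obs, , drop = FALSE] %*% model$beta_cov[, j]) else 0
    z <- (y[obs] - fit_cov - model$alpha[j]) / model$sigma[j]
    g <- model$gamma_star[cbind(site_i[obs], j)]
    d <- model$delta_star[cbind(site_i[obs], j)]
    table[[v]][obs] <- model$sigma[j] * (z - g) / d + fit_cov +
      model$alpha[j]
  }
  table
}

#' Serialize a harmonization model to JSON
#' @param model a `combat_gam` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  strip <- function(M) {
    df <- as.data.frame(M)
    rownames(df) <- NULL
    df
  }
  obj$cov_terms <- rownames(obj$beta_cov)
  obj$beta_cov <- strip(obj$beta_cov)
  for (f in c("gamma_star", "delta_star", "gamma_hat", "delta2_hat",
              "n_site_metric"))
    obj[[f]] <- strip(obj[[f]])
  obj$spec <- unclass(obj$spec)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a harmonization model from JSON
#' @param path file written by [write_combat_model()].
#' @return a `combat_gam` model.
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(df) {
    M <- as.matrix(as.data.frame(df))
    rownames(M) <- obj$sites
    colnames(M) <- obj$metrics
    M
  }
  for (f in c("gamma_star", "delta_star", "gamma_hat", "delta2_hat",
              "n_site_metric"))
    obj[[f]] <- rebuild(obj[[f]])
  obj$beta_cov <- {
    M <- as.matrix(as.data.frame(obj$beta_cov))
    dimnames(M) <- list(obj$cov_terms, obj$metrics)
    M
  }
  obj$alpha <- stats::setNames(unlist(obj$alpha), obj$metrics)
  obj$sigma <- stats::setNames(unlist(obj$sigma), obj$metrics)
  obj$spline_defs <- lapply(obj$spline_defs, function(d)
    list(knots = unlist(d$knots), boundary = unlist(d$boundary),
         degree = d$degree))
  obj$spec <- structure(lapply(obj$spec, function(x)
    if (is.null(x)) character(0) else unlist(x)), class = "covariate_spec")
  structure(obj, class = "combat_gam")
}
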