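#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) with midrank tie handling.
#'
#' @param scores numeric risk scores (larger = more positive-class).
#' @param labels 0/1 or logical labels.
#' @return ROC-AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall, processing tied scores as
#' blocks; for a constant scorer this equals the positive-class prevalence,
#' the PR-AUC chance baseline.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  blocks <- cumsum(!duplicated(s))
  tp_b <- tapply(y, blocks, sum)
  n_b <- tapply(rep(1, length(y)), blocks, sum)
  tp <- cumsum(tp_b)
  nn <- cumsum(n_b)
  prec <- tp / nn
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' PR-AUC chance baseline
#' @param n_pos,n_neg class counts.
#' @return positive-class prevalence `n_pos / (n_pos + n_neg)`.
#' @export
prauc_baseline <- function(n_pos, n_neg) n_pos / (n_pos + n_neg)

# Stratified fold assignment: shuffle within each stratum, round-robin.
stratified_folds <- function(strata, k, seed) {
  fold <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  fold
}

#' Classification pipeline configuration
#'
#' @param task `"AN_vs_HC"` or `"ANR_vs_ANBP"`; sets the confound set (age
#'   always, BMI for the subtype task, ICV for SA/SV features) and the
#'   label.
#' @param pca_grid numbers of principal components to search; `Inf` means
#'   all available components.
#' @param cost_grid SVM cost values.
#' @param outer_folds,inner_folds cross-validation folds.
#' @param harmonize fit ComBat-GAM inside training folds (TRUE for nested
#'   CV; leave-site-out runs force FALSE).
#' @param n_permutations label permutations for significance testing.
#' @param seed integer seed controlling folds and permutations.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(task = c("AN_vs_HC", "ANR_vs_ANBP"),
                            pca_grid = c(10, 20, 40, 80, Inf),
                            cost_grid = c(0.01, 0.1, 1, 10),
                            outer_folds = 10, inner_folds = 10,
                            harmonize = TRUE, n_permutations = 1000,
                            seed = 1) {
  task <- match.arg(task)
  if (!length(pca_grid) || !length(cost_grid)) stop("grids must be non-empty")
  structure(list(task = task, pca_grid = pca_grid, cost_grid = cost_grid,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 harmonize = harmonize, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train-only linear confound regression
#'
#' Per feature, fits a linear regression on the confounds using training
#' rows only and returns residuals for both training and test rows (test
#' residuals use the training coefficients). Constant confounds are dropped
#' with a warning; with zero confounds the features pass through unchanged.
#'
#' @param train,test numeric feature matrices (test may be NULL).
#' @param conf_train,conf_test confound matrices aligned with the rows.
#' @return list with `train`, `test` residual matrices and `coefs`.
#' @export
confound_regress <- function(train, test = NULL, conf_train,
                             conf_test = NULL) {
  train <- as.matrix(train)
  if (is.null(conf_train) || ncol(as.matrix(conf_train)) == 0) {
    return(list(train = train, test = test, coefs = NULL))
  }
  C <- as.matrix(conf_train)
  keep <- apply(C, 2, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning("dropping constant confound(s): ",
            paste(colnames(C)[!keep], collapse = ", "))
    C <- C[, keep, drop = FALSE]
  }
  if (ncol(C) == 0) return(list(train = train, test = test, coefs = NULL))
  X <- cbind(1, C)
  B <- qr.coef(qr(X), train)
  B[is.na(B)] <- 0
  out_tr <- train - X %*% B
  out_te <- NULL
  if (!is.null(test)) {
    Ct <- as.matrix(conf_test)[, keep, drop = FALSE]
    out_te <- as.matrix(test) - cbind(1, Ct) %*% B
  }
  list(train = out_tr, test = out_te, coefs = B)
}

# Confound matrix for a task: age always; BMI for the subtype task; ICV is
# handled separately per feature family (regressed from SA/SV features).
task_confounds <- function(table, task) {
  M <- cbind(age = table$age)
  if (task == "ANR_vs_ANBP") M <- cbind(M, bmi = table$bmi)
  M
}

# Class-weighted L2-regularized squared-hinge linear SVM, deterministic
# BFGS fit. Weights are inverse class frequencies.
svm_fit <- function(X, y01, cost) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- length(y)
  cw <- n / (2 * ifelse(y01 == 1, sum(y01 == 1), sum(y01 == 0)))
  d <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(d)]
    b <- par[d + 1]
    m <- pmax(0, 1 - y * (X %*% w + b))
    0.5 * sum(w^2) + cost * sum(cw * m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(d)]
    b <- par[d + 1]
    m <- pmax(0, 1 - y * as.vector(X %*% w + b))
    gsc <- -2 * cost * cw * m * y
    c(w + as.vector(crossprod(X, gsc)), sum(gsc))
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  w <- fit$par[seq_len(d)]
  list(w = w, b = fit$par[d + 1],
       norm = max(sqrt(sum(w^2)), 1e-12))
}

# Signed distance to the hyperplane: the continuous risk score.
svm_score <- function(model, X) {
  (as.vector(X %*% model$w) + model$b) / model$norm
}

# Label vector for a task; subtype task keeps only labelled AN rows.
task_labels <- function(table, task) {
  if (task == "AN_vs_HC") {
    list(table = table, y = as.integer(table$group == "AN"))
  } else {
    tb <- subtype_rows(table)
    list(table = tb, y = as.integer(tb$subtype == "AN-R"))
  }
}

# Shared preprocessing fitted on training rows only: optional ComBat-GAM,
# confound regression (age [+BMI]; ICV additionally for SA/SV features),
# train-mean imputation, standardization. Returns processed matrices.
prep_features <- function(train_tbl, test_tbl, task, harmonize) {
  man <- table_manifest(train_tbl)
  feats <- intersect(metric_names(man, mega_only = TRUE), names(train_tbl))
  if (harmonize) {
    retain <- if (task == "AN_vs_HC") "group" else "subtype"
    spec <- covariate_spec(smooth_terms = "age",
                           linear_terms = c("bmi", "icv"),
                           retained_factors = retain)
    cm <- fit_combat_gam(train_tbl, spec, metrics = feats)
    train_tbl <- apply_combat_gam(cm, train_tbl)
    if (!is.null(test_tbl)) test_tbl <- apply_combat_gam(cm, test_tbl)
  }
  Xtr <- metric_matrix(train_tbl, feats)
  Xte <- if (!is.null(test_tbl)) metric_matrix(test_tbl, feats) else NULL
  # train-mean imputation of missing cells
  mu <- colMeans(Xtr, na.rm = TRUE)
  for (j in seq_along(feats)) {
    Xtr[is.na(Xtr[, j]), j] <- mu[j]
    if (!is.null(Xte)) Xte[is.na(Xte[, j]), j] <- mu[j]
  }
  conf_tr <- task_confounds(train_tbl, task)
  conf_te <- if (!is.null(test_tbl)) task_confounds(test_tbl, task) else NULL
  fam <- man$family[match(feats, man$metric)]
  icv_feats <- fam %in% c("SA", "SV")
  r1 <- confound_regress(Xtr[, !icv_feats, drop = FALSE],
                         if (is.null(Xte)) NULL else
                           Xte[, !icv_feats, drop = FALSE],
                         conf_tr, conf_te)
  r2 <- confound_regress(Xtr[, icv_feats, drop = FALSE],
                         if (is.null(Xte)) NULL else
                           Xte[, icv_feats, drop = FALSE],
                         cbind(conf_tr, icv = train_tbl$icv),
                         if (is.null(conf_te)) NULL else
                           cbind(conf_te, icv = test_tbl$icv))
  Xtr <- cbind(r1$train, r2$train)
  Xte <- if (!is.null(Xte)) cbind(r1$test, r2$test) else NULL
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  if (!is.null(Xte)) Xte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
  list(train = Xtr, test = Xte)
}

# PCA via SVD on the (already centred/standardized) training matrix.
pca_fit <- function(X, max_k) {
  k <- min(nrow(X) - 1L, ncol(X), max_k)
  sv <- svd(X, nu = 0, nv = k)
  sv$v
}

grid_combos <- function(config) {
  expand.grid(k = config$pca_grid, cost = config$cost_grid,
              KEEP.OUT.ATTRS = FALSE)
}

# One train/test evaluation for a fixed grid point; rotation is the full
# PCA rotation, truncated per k.
eval_grid <- function(Xtr, ytr, Xte, yte, rotation, combos) {
  sapply(seq_len(nrow(combos)), function(g) {
    k <- min(combos$k[g], ncol(rotation))
    R <- rotation[, seq_len(k), drop = FALSE]
    mod <- svm_fit(Xtr %*% R, ytr, combos$cost[g])
    sc <- svm_score(mod, Xte %*% R)
    pr_auc(sc, yte)
  })
}

#' Nested cross-validated classification
#'
#' Outer stratified k-fold for performance estimation; inner stratified
#' k-fold grid search maximizing PR-AUC for the number of PCA components
#' and the SVM cost. Harmonization (when enabled), confound regression,
#' imputation, standardization, PCA and the class-weighted linear SVM are
#' all fitted on training folds only and applied to the held-out fold.
#' Folds are stratified by class within site.
#'
#' @param table a `morpho_table` (raw, unharmonized).
#' @param config a [pipeline_config()].
#' @return a `classification_result`: per-fold metrics and chosen
#'   hyperparameters, pooled ROC-AUC and PR-AUC, and one held-out risk
#'   score per participant.
#' @export
nested_cv <- function(table, config) {
  tl <- task_labels(table, config$task)
  tb <- tl$table
  y <- tl$y
  if (length(unique(y)) < 2) stop("both classes must be present")
  folds <- stratified_folds(interaction(tb$site, y, drop = TRUE),
                            config$outer_folds,
                            child_seed(config$seed, "outer_folds"))
  if (any(tapply(y, folds, function(g) length(unique(g))) < 2))
    stop("stratification infeasible: a fold contains one class")
  combos <- grid_combos(config)
  scores <- rep(NA_real_, length(y))
  fold_rows <- list()
  for (f in sort(unique(folds))) {
    te <- folds == f
    tr_tbl <- tb[!te, , drop = FALSE]
    te_tbl <- tb[te, , drop = FALSE]
    ytr <- y[!te]
    best <- c(k = combos$k[1], cost = combos$cost[1])
    if (nrow(combos) > 1) {
      inner <- stratified_folds(
        interaction(tr_tbl$site, ytr, drop = TRUE), config$inner_folds,
        child_seed(config$seed, paste0("inner_folds", f)))
      perf <- matrix(0, nrow(combos), 0)
      for (i in sort(unique(inner))) {
        ite <- inner == i
        if (length(unique(ytr[ite])) < 2 || length(unique(ytr[!ite])) < 2)
          next
        pp <- prep_features(tr_tbl[!ite, , drop = FALSE],
                            tr_tbl[ite, , drop = FALSE],
                            config$task, config$harmonize)
        rot <- pca_fit(pp$train, max(combos$k[is.finite(combos$k)],
                                     min(dim(pp$train))))
        perf <- cbind(perf, eval_grid(pp$train, ytr[!ite], pp$test,
                                      ytr[ite], rot, combos))
      }
      mp <- rowMeans(perf, na.rm = TRUE)
      bi <- which.max(mp)  # ties: first grid point, deterministic
      best <- c(k = combos$k[bi], cost = combos$cost[bi])
    }
    pp <- prep_features(tr_tbl, te_tbl, config$task, config$harmonize)
    rot <- pca_fit(pp$train, best[["k"]])
    mod <- svm_fit(pp$train %*% rot, ytr, best[["cost"]])
    sc <- svm_score(mod, pp$test %*% rot)
    scores[te] <- sc
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = f, n_test = sum(te),
      roc_auc = roc_auc(sc, y[te]), pr_auc = pr_auc(sc, y[te]),
      k = best[["k"]], cost = best[["cost"]])
  }
  structure(list(task = config$task, mode = "nested",
                 folds = do.call(rbind, fold_rows),
                 pooled_roc_auc = roc_auc(scores, y),
                 pooled_pr_auc = pr_auc(scores, y),
                 scores = scores, labels = y,
                 participant_id = tb$participant_id, config = config),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (%s CV)\n", x$task, x$mode))
  cat(sprintf("  pooled ROC-AUC = %.3f, pooled PR-AUC = %.3f (baseline %.3f)\n",
              x$pooled_roc_auc, x$pooled_pr_auc, mean(x$labels)))
  invisible(x)
}

#' Leave-site(s)-out cross-validated classification
#'
#' Folds are site partitions: each held-out fold is one site, never seen in
#' training, and no harmonization stage is used (site parameters cannot be
#' estimated for unseen sites). Hyperparameters are chosen by stratified
#' grid search within the training sites. A held-out site containing a
#' single class contributes risk scores to the pooled metrics but reports
#' fold-level AUCs as NA with a caveat message.
#'
#' @param table a `morpho_table` with at least 4 sites.
#' @param config a [pipeline_config()]; `harmonize` is forced off.
#' @return a `classification_result` with mode `"lsso"`.
#' @export
lsso_cv <- function(table, config) {
  tl <- task_labels(table, config$task)
  tb <- tl$table
  y <- tl$y
  sites <- unique(tb$site)
  if (length(sites) < 4) stop("leave-site-out requires at least 4 sites")
  config$harmonize <- FALSE
  combos <- grid_combos(config)
  scores <- rep(NA_real_, length(y))
  fold_rows <- list()
  for (f in seq_along(sites)) {
    te <- tb$site == sites[f]
    tr_tbl <- tb[!te, , drop = FALSE]
    ytr <- y[!te]
    best <- c(k = combos$k[1], cost = combos$cost[1])
    if (nrow(combos) > 1) {
      inner <- stratified_folds(
        interaction(tr_tbl$site, ytr, drop = TRUE),
        min(config$inner_folds, 5),
        child_seed(config$seed, paste0("lsso_inner", f)))
      perf <- matrix(0, nrow(combos), 0)
      for (i in sort(unique(inner))) {
        ite <- inner == i
        if (length(unique(ytr[ite])) < 2 || length(unique(ytr[!ite])) < 2)
          next
        pp <- prep_features(tr_tbl[!ite, , drop = FALSE],
                            tr_tbl[ite, , drop = FALSE], config$task, FALSE)
        rot <- pca_fit(pp$train, max(combos$k[is.finite(combos$k)],
                                     min(dim(pp$train))))
        perf <- cbind(perf, eval_grid(pp$train, ytr[!ite], pp$test,
                                      ytr[ite], rot, combos))
      }
      mp <- rowMeans(perf, na.rm = TRUE)
      bi <- which.max(mp)
      best <- c(k = combos$k[bi], cost = combos$cost[bi])
    }
    pp <- prep_features(tr_tbl, tb[te, , drop = FALSE], config$task, FALSE)
    rot <- pca_fit(pp$train, best[["k"]])
    mod <- svm_fit(pp$train %*% rot, ytr, best[["cost"]])
    sc <- svm_score(mod, pp$test %*% rot)
    scores[te] <- sc
    one_class <- length(unique(y[te])) < 2
    if (one_class)
      message("held-out site ", sites[f],
              " contains a single class; fold AUCs not defined")
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = f, site = sites[f], n_test = sum(te),
      roc_auc = if (one_class) NA_real_ else roc_auc(sc, y[te]),
      pr_auc = if (one_class) NA_real_ else pr_auc(sc, y[te]),
      k = best[["k"]], cost = best[["cost"]])
  }
  structure(list(task = config$task, mode = "lsso",
                 folds = do.call(rbind, fold_rows),
                 pooled_roc_auc = roc_auc(scores, y),
                 pooled_pr_auc = pr_auc(scores, y),
                 scores = scores, labels = y,
                 participant_id = tb$participant_id, config = config),
            class = "classification_result")
}

#' Permute class labels within site
#'
#' @param table a `morpho_table`.
#' @param task classification task (determines which label is permuted).
#' @param seed integer seed.
#' @return the table with permuted `group` (or `subtype`) labels; per-site
#'   label counts are invariant.
#' @export
permute_labels_within_site <- function(table, task = "AN_vs_HC", seed = 1) {
  col <- if (task == "AN_vs_HC") "group" else "subtype"
  with_seed(seed, {
    for (s in unique(table$site)) {
      idx <- which(table$site == s)
      if (col == "subtype")
        idx <- idx[table$group[idx] == "AN" &
                     table$subtype[idx] %in% c("AN-R", "AN-BP")]
      table[[col]][idx] <- table[[col]][idx][sample.int(length(idx))]
    }
  })
  table
}

#' Permutation test of classification performance
#'
#' Labels are permuted within site and the full cross-validated pipeline is
#' re-run for each permutation;
#' `p = (1 + #[perm >= observed]) / (1 + n_permutations)`.
#'
#' @param table a `morpho_table`.
#' @param config a [pipeline_config()] (`n_permutations >= 99`).
#' @param observed observed pooled metric; computed via [nested_cv()] /
#'   [lsso_cv()] when NULL.
#' @param metric `"pr_auc"` (optimization metric) or `"roc_auc"`.
#' @param mode `"nested"` or `"lsso"`.
#' @return list with `p`, `observed`, and the permutation null values.
#' @export
permutation_test <- function(table, config, observed = NULL,
                             metric = c("pr_auc", "roc_auc"),
                             mode = c("nested", "lsso")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (config$n_permutations < 99) stop("n_permutations must be >= 99")
  runner <- if (mode == "nested") nested_cv else lsso_cv
  field <- paste0("pooled_", metric)
  if (is.null(observed)) observed <- runner(table, config)[[field]]
  perm <- vapply(seq_len(config$n_permutations), function(b) {
    ptab <- permute_labels_within_site(
      table, config$task, child_seed(config$seed, paste0("perm", b)))
    runner(ptab, config)[[field]]
  }, numeric(1))
  list(p = (1 + sum(perm >= observed)) / (1 + config$n_permutations),
       observed = observed, null = perm, metric = metric)
}

#' Forward-model (Haufe) feature importances
#'
#' Importance of each feature is the Pearson correlation between the
#' feature and the held-out machine-learning risk score: positive values
#' mean larger feature values push the score toward the positive class.
#' Significance is assessed by permuting the risk scores across
#' participants, with Benjamini-Hochberg FDR across features;
#' zero-variance features are flagged with undefined importance.
#'
#' @param features participant x feature matrix (values as entered into
#'   the classifier, held-out rows only).
#' @param risk_scores held-out risk scores aligned with the rows.
#' @param n_perm score permutations (default 1000).
#' @param seed integer seed.
#' @param alpha FDR level.
#' @return data.frame per feature: `importance`, `p`, `q`, `significant`,
#'   `degenerate`.
#' @export
haufe_importance <- function(features, risk_scores, n_perm = 1000,
                             seed = 1, alpha = 0.05) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(risk_scores))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  degen <- !is.finite(sds) | sds == 0
  r <- rep(NA_real_, ncol(X))
  ok_cols <- which(!degen)
  r[ok_cols] <- suppressWarnings(
    as.vector(stats::cor(X[, ok_cols, drop = FALSE], risk_scores,
                         use = "pairwise.complete.obs")))
  exceed <- rep(0L, ncol(X))
  with_seed(child_seed(seed, "haufe_perm"), {
    for (b in seq_len(n_perm)) {
      rp <- suppressWarnings(as.vector(
        stats::cor(X[, ok_cols, drop = FALSE],
                   risk_scores[sample.int(length(risk_scores))],
                   use = "pairwise.complete.obs")))
      exceed[ok_cols] <- exceed[ok_cols] + (abs(rp) >= abs(r[ok_cols]))
    }
  })
  p <- rep(NA_real_, ncol(X))
  p[ok_cols] <- (1 + exceed[ok_cols]) / (1 + n_perm)
  q <- rep(NA_real_, ncol(X))
  if (length(ok_cols)) q[ok_cols] <- bh_fdr(p[ok_cols])$q
  data.frame(feature = colnames(X), importance = r, p = p, q = q,
             significant = !is.na(q) & q < alpha, degenerate = degen)
}

# Ridge-regularized logistic deviance, used as a separation-safe fallback.
logistic_deviance <- function(X, y, lambda = 0) {
  X <- cbind(1, as.matrix(X))
  nll <- function(beta) {
    eta <- as.vector(X %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * lambda * sum(beta[-1]^2)
  }
  gr <- function(beta) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    as.vector(crossprod(X, mu - y)) + c(0, lambda * beta[-1])
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  eta <- as.vector(X %*% fit$par)
  mu <- 1 / (1 + exp(-eta))
  if (lambda == 0 && any(mu > 1 - 1e-8 | mu < 1e-8)) {
    warning("separation in logistic fit; refitting with ridge penalty")
    return(logistic_deviance(as.matrix(X)[, -1, drop = FALSE], y,
                             lambda = 1e-3))
  }
  2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}

#' A-posteriori confound deviance analysis
#'
#' Quantifies how much of the label information in the risk score is not
#' explained by confounds: logistic models `label ~ confounds` (deviance
#' D0) and `label ~ confounds + risk score` (D1) give
#' `proportion = (D0 - D1) / D0`. Significance is assessed by permuting the
#' risk scores within confound strata (quantile bins of the confound-only
#' linear predictor).
#'
#' @param risk_scores held-out risk scores.
#' @param confounds matrix/data.frame of confound columns.
#' @param labels 0/1 labels.
#' @param n_perm permutations (default 999).
#' @param n_strata confound strata for the permutation (default 5).
#' @param seed integer seed.
#' @return list with `proportion`, `p`, and the permutation null.
#' @export
confound_deviance <- function(risk_scores, confounds, labels, n_perm = 999,
                              n_strata = 5, seed = 1) {
  y <- as.integer(labels)
  C <- as.matrix(confounds)
  d0 <- logistic_deviance(C, y)
  d1 <- logistic_deviance(cbind(C, score = risk_scores), y)
  prop <- (d0 - d1) / d0
  # strata from the confound-only linear predictor
  eta <- as.vector(cbind(1, C) %*%
                     stats::glm.fit(cbind(1, C), y,
                                    family = stats::binomial())$coefficients)
  strata <- cut(eta, breaks = unique(stats::quantile(
    eta, probs = seq(0, 1, length.out = n_strata + 1))),
    include.lowest = TRUE, labels = FALSE)
  null <- with_seed(child_seed(seed, "confdev_perm"), {
    vapply(seq_len(n_perm), function(b) {
      sp <- risk_scores
      for (s in unique(strata)) {
        idx <- which(strata == s)
        sp[idx] <- sp[idx][sample.int(length(idx))]
      }
      (d0 - logistic_deviance(cbind(C, score = sp), y)) / d0
    }, numeric(1))
  })
  list(proportion = prop, p = (1 + sum(null >= prop)) / (1 + n_perm),
       null = null)
}
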