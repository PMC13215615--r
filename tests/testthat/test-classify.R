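test_that("ROC-AUC and PR-AUC behave on known inputs", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), y), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), y), 0)
  expect_equal(roc_auc(c(1, 3, 2, 4), y), 0.75)
  # constant scorer: ROC 0.5, PR equals prevalence (the chance baseline)
  y2 <- rep(c(1, 0), c(30, 70))
  expect_equal(roc_auc(rep(0, 100), y2), 0.5)
  expect_equal(pr_auc(rep(0, 100), y2), 0.3)
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), y <- c(1, 1, 0, 0)), 1)
  expect_equal(prauc_baseline(570, 739), 570 / 1309)
})

test_that("PR-AUC of an uninformative scorer concentrates at prevalence", {
  set.seed(90)
  y <- rep(c(1, 0), c(40, 120))
  ap <- replicate(300, pr_auc(rnorm(160), y))
  expect_lt(abs(mean(ap) - 0.25), 0.03)
})

test_that("confound regression honours the train/test contract", {
  set.seed(91)
  n <- 1000
  age <- rnorm(n, 20, 5)
  f <- 2 * age + rnorm(n)
  r <- confound_regress(cbind(f = f), NULL, cbind(age = age))
  expect_lt(abs(cor(r$train[, 1], age)), 0.02)
  # test rows residualized with training coefficients
  tr <- 1:500; te <- 501:1000
  r2 <- confound_regress(cbind(f = f[tr]), cbind(f = f[te]),
                         cbind(age = age[tr]), cbind(age = age[te]))
  B <- r2$coefs
  expect_equal(as.vector(r2$test),
               f[te] - as.vector(cbind(1, age[te]) %*% B), tolerance = 1e-12)
  # zero confounds: identity; constant confound dropped with warning
  r3 <- confound_regress(cbind(f = f), NULL,
                         matrix(numeric(0), n, 0))
  expect_identical(r3$train[, 1], f)
  expect_warning(
    confound_regress(cbind(f = f), NULL, cbind(k = rep(1, n), age = age)),
    "constant")
})

test_that("linear SVM separates and scores deterministically", {
  set.seed(92)
  X <- rbind(matrix(rnorm(100, -1), 50), matrix(rnorm(100, 1), 50))
  y <- rep(c(0, 1), each = 50)
  m1 <- svm_fit(X, y, cost = 1)
  m2 <- svm_fit(X, y, cost = 1)
  expect_identical(m1$w, m2$w)
  sc <- svm_score(m1, X)
  expect_gt(roc_auc(sc, y), 0.9)  # Bayes-optimal direction gives ~0.94 here
  # class weighting: imbalanced null data should not collapse to majority
  Xn <- matrix(rnorm(400), 200)
  yn <- rep(c(1, 0), c(30, 170))
  mn <- svm_fit(Xn, yn, cost = 1)
  expect_true(is.finite(mn$b))
})

test_that("nested CV is deterministic and leakage-safe", {
  tab <- small_cohort()
  cfg <- fast_clf(seed = 7)
  r1 <- nested_cv(tab, cfg)
  r2 <- nested_cv(tab, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$pooled_roc_auc, r2$pooled_roc_auc)
  # every participant scored exactly once
  expect_false(anyNA(r1$scores))
  expect_identical(length(r1$scores), nrow(tab))
  expect_true(r1$pooled_roc_auc >= 0 && r1$pooled_roc_auc <= 1)
  # informative default cohort: clearly above chance
  expect_gt(r1$pooled_roc_auc, 0.70)
})

test_that("corrupting a held-out fold leaves training parameters intact", {
  # the leakage audit: rebuild the preprocessing exactly as fold 1 of
  # nested_cv does, corrupt the held-out rows, and compare every fitted
  # parameter
  tab <- small_cohort()
  folds <- morphodev:::stratified_folds(
    interaction(tab$site, tab$group, drop = TRUE), 5,
    child_seed(7, "outer_folds"))
  te <- folds == 1
  train <- tab[!te, , drop = FALSE]
  test <- tab[te, , drop = FALSE]
  test_bad <- test
  for (v in metric_names(table_manifest(tab), mega_only = TRUE))
    test_bad[[v]] <- test_bad[[v]] * 5 + 100
  spec <- covariate_spec("age", c("bmi", "icv"), "group")
  feats <- metric_names(table_manifest(tab), mega_only = TRUE)
  m1 <- fit_combat_gam(train, spec, metrics = feats)
  m2 <- fit_combat_gam(train, spec, metrics = feats)
  expect_identical(m1, m2)
  p1 <- morphodev:::prep_features(train, test, "AN_vs_HC", TRUE)
  p2 <- morphodev:::prep_features(train, test_bad, "AN_vs_HC", TRUE)
  expect_identical(p1$train, p2$train)  # training matrix untouched
  rot1 <- morphodev:::pca_fit(p1$train, 10)
  rot2 <- morphodev:::pca_fit(p2$train, 10)
  expect_identical(rot1, rot2)
  sv1 <- morphodev:::svm_fit(p1$train %*% rot1,
                             as.integer(train$group == "AN"), 1)
  sv2 <- morphodev:::svm_fit(p2$train %*% rot2,
                             as.integer(train$group == "AN"), 1)
  expect_identical(sv1$w, sv2$w)
})

test_that("label permutation within site preserves per-site counts", {
  tab <- small_cohort()
  perm <- permute_labels_within_site(tab, "AN_vs_HC", seed = 31)
  expect_identical(table(perm$site, perm$group), table(tab$site, tab$group))
  expect_false(identical(perm$group, tab$group))
  # permuted labels: chance-level performance
  cfg <- fast_clf(seed = 8)
  r <- nested_cv(perm, cfg)
  expect_lt(abs(r$pooled_roc_auc - 0.5), 0.12)
})

test_that("permutation test p-values follow the add-one formula", {
  tab <- generate_cohort(small_cohort_config(n = 120, n_sites = 2,
                                             seed = 33))
  cfg <- pipeline_config("AN_vs_HC", pca_grid = 10, cost_grid = 1,
                         outer_folds = 3, inner_folds = 2,
                         n_permutations = 99, seed = 5)
  pt <- permutation_test(tab, cfg, observed = 2)  # above any null value
  expect_equal(pt$p, 1 / 100)
  expect_identical(length(pt$null), 99L)
  expect_error(
    permutation_test(tab, pipeline_config(n_permutations = 50)),
    ">= 99")
})

test_that("leave-site-out honours its contracts", {
  tab <- generate_cohort(small_cohort_config(n = 360, n_sites = 4,
                                             seed = 44))
  expect_error(lsso_cv(generate_cohort(small_cohort_config(
    n = 120, n_sites = 2, seed = 45)), fast_clf()), "4 sites")
  cfg <- pipeline_config("AN_vs_HC", pca_grid = c(10, 20), cost_grid = 1,
                         outer_folds = 4, inner_folds = 3, seed = 9)
  r <- lsso_cv(tab, cfg)
  expect_identical(nrow(r$folds), 4L)
  expect_identical(sort(r$folds$site), sort(unique(tab$site)))
  expect_false(anyNA(r$scores))
  # single-class held-out site: fold AUC undefined but run completes
  tab2 <- tab
  drop <- tab2$site == "site01" & tab2$group == "AN"
  tab2 <- tab2[!drop, , drop = FALSE]
  expect_message(r2 <- lsso_cv(tab2, cfg), "single class")
  expect_true(is.na(r2$folds$roc_auc[r2$folds$site == "site01"]))
})

test_that("site effects hurt LSsO more than in-fold harmonization", {
  base <- small_cohort_config(n = 360, n_sites = 4, seed = 55)
  base$sites$shift <- c(-2, -0.7, 0.7, 2)  # shifts dwarfing group effects
  tab <- generate_cohort(base)
  cfg <- pipeline_config("AN_vs_HC", pca_grid = 20, cost_grid = 1,
                         outer_folds = 4, inner_folds = 2, seed = 10)
  r_nested <- nested_cv(tab, cfg)
  r_lsso <- lsso_cv(tab, cfg)
  expect_gt(r_nested$pooled_roc_auc, r_lsso$pooled_roc_auc)
  # no-batch limit: the two pipelines agree
  base0 <- small_cohort_config(n = 360, n_sites = 4, seed = 56)
  base0$sites$shift[] <- 0
  base0$sites$scale[] <- 1
  tab0 <- generate_cohort(base0)
  expect_lt(abs(nested_cv(tab0, cfg)$pooled_roc_auc -
                  lsso_cv(tab0, cfg)$pooled_roc_auc), 0.05)
})

test_that("Haufe importances recover signs and control false positives", {
  set.seed(60)
  n <- 400
  score <- rnorm(n)
  X <- cbind(parietal = -0.9 * score + rnorm(n),
             temporalpole = 0.2 * score + rnorm(n),
             noise1 = rnorm(n), noise2 = rnorm(n),
             flat = rep(1, n))
  imp <- haufe_importance(X, score, n_perm = 300, seed = 3)
  expect_lt(imp$importance[1], 0)
  expect_gt(imp$importance[2], 0)
  expect_gt(abs(imp$importance[1]), abs(imp$importance[2]))
  expect_true(all(imp$significant[1:2]))
  expect_true(imp$degenerate[5])
  expect_true(is.na(imp$importance[5]))
  # feature identical to the score: importance 1
  imp1 <- haufe_importance(cbind(s = score), score, n_perm = 100, seed = 4)
  expect_equal(imp1$importance, 1)
  # independent score: FDR keeps the significant fraction small
  imp0 <- haufe_importance(matrix(rnorm(n * 40), n), rnorm(n),
                           n_perm = 300, seed = 5)
  expect_lte(mean(imp0$significant), 0.05)
})

test_that("confound deviance separates explained from novel signal", {
  set.seed(61)
  n <- 1000
  age <- rnorm(n, 20, 4)
  y <- rbinom(n, 1, stats::plogis(0.4 * scale(age)))
  # score that is a pure age proxy: proportion ~ 0
  cd_age <- confound_deviance(2 * age + rnorm(n, 0, 0.1),
                              cbind(age = age), y, n_perm = 99, seed = 1)
  expect_lt(cd_age$proportion, 0.01)
  # informative score orthogonal to age
  sig <- rbinom(n, 1, 0.5)
  y2 <- ifelse(sig == 1, y, rbinom(n, 1, 0.5))
  sc <- sig * (2 * y2 - 1) + rnorm(n, 0, 0.5)
  cd_sig <- confound_deviance(sc, cbind(age = age), y2, n_perm = 99,
                              seed = 2)
  expect_gt(cd_sig$proportion, 0)
  expect_lt(cd_sig$p, 0.05)
})
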