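# direct-formula two-batch ComBat oracle (no EB): standardize against the
# pooled covariate-free model, centre/rescale each batch, restore scale
combat_two_batch_oracle <- function(y, batch) {
  sites <- sort(unique(batch))
  m_i <- tapply(y, batch, mean)
  n_i <- tapply(y, batch, length)
  alpha <- sum(n_i / sum(n_i) * m_i)
  sigma <- sqrt(mean((y - m_i[batch])^2))
  z <- (y - alpha) / sigma
  g_i <- tapply(z, batch, mean)
  d_i <- tapply(z, batch, sd)
  sigma * (z - g_i[batch]) / d_i[batch] + alpha
}

test_that("EB-off two-batch adjustment matches the closed-form oracle", {
  set.seed(11)
  n <- 80
  batch <- rep(c("a", "b"), each = n / 2)
  y <- rnorm(n, 10, 2) + 1.5 * (batch == "b")
  df <- toy_table(n, seed = 12, sites = "s1")
  df$site <- batch
  df$ct_lh_bankssts <- y
  model <- fit_combat_gam(df, covariate_spec(character(0)),
                          metrics = "ct_lh_bankssts", eb = FALSE)
  adj <- apply_combat_gam(model, df)
  expect_equal(adj$ct_lh_bankssts,
               as.vector(combat_two_batch_oracle(y, factor(batch))),
               tolerance = 1e-10)
})

test_that("single-site harmonization is the identity", {
  tab <- toy_table(50, seed = 3)
  model <- fit_combat_gam(tab, covariate_spec("age"))
  adj <- apply_combat_gam(model, tab)
  expect_equal(adj$ct_lh_bankssts, tab$ct_lh_bankssts, tolerance = 1e-8)
  expect_equal(adj$sv_lh_thalamus, tab$sv_lh_thalamus, tolerance = 1e-8)
})

test_that("pure site mean shift is removed (EB on)", {
  set.seed(21)
  n <- 1000
  tab <- toy_table(n, seed = 22, sites = c("a", "b"))
  delta <- 0.8  # injected shift, in units of the residual SD 0.15
  tab$ct_lh_bankssts <- rnorm(n, 2.5, 0.15) +
    delta * 0.15 * (tab$site == "b")
  tab$sv_lh_thalamus <- rnorm(n, 7000, 700) +
    delta * 700 * (tab$site == "b")
  model <- fit_combat_gam(tab, covariate_spec(character(0)))
  adj <- apply_combat_gam(model, tab)
  for (v in c("ct_lh_bankssts", "sv_lh_thalamus")) {
    gap <- diff(tapply(adj[[v]], adj$site, mean))
    expect_lt(abs(gap) / sd(adj[[v]]), 0.05)
  }
})

test_that("a group effect orthogonal to site is preserved", {
  set.seed(31)
  n <- 1000
  tab <- toy_table(n, seed = 32, sites = c("a", "b"))
  # alternate groups within site so group is balanced across sites
  d_true <- -0.5
  tab$ct_lh_bankssts <- rnorm(n, 2.5, 0.15) +
    0.15 * (tab$site == "b") + d_true * 0.15 * (tab$group == "AN")
  model <- fit_combat_gam(
    tab, covariate_spec(character(0), retained_factors = "group"),
    metrics = "ct_lh_bankssts")
  adj <- apply_combat_gam(model, tab)
  y1 <- adj$ct_lh_bankssts[adj$group == "AN"]
  y0 <- adj$ct_lh_bankssts[adj$group == "HC"]
  sp <- sqrt((var(y1) + var(y0)) / 2)
  expect_lt(abs((mean(y1) - mean(y0)) / sp - d_true), 0.05)
})

test_that("site-wise residual variances are equalized on training data", {
  set.seed(41)
  n <- 1000
  tab <- toy_table(n, seed = 42, sites = c("a", "b"))
  tab$ct_lh_bankssts <- rnorm(n, 2.5, ifelse(tab$site == "a", 0.12, 0.22))
  model <- fit_combat_gam(tab, covariate_spec(character(0)),
                          metrics = "ct_lh_bankssts")
  adj <- apply_combat_gam(model, tab)
  v <- tapply(adj$ct_lh_bankssts, adj$site, var)
  expect_lt(abs(v[["a"]] / v[["b"]] - 1), 0.05)
})

test_that("the fitted age smooth survives harmonization", {
  tab <- small_cohort()
  spec <- covariate_spec("age", retained_factors = "group")
  model <- fit_combat_gam(tab, spec, metrics = "ct_lh_precuneus")
  adj <- apply_combat_gam(model, tab)
  sm_in <- stats::lm(ct_lh_precuneus ~ splines::bs(age, df = 5),
                     data = as.data.frame(tab))
  sm_out <- stats::lm(ct_lh_precuneus ~ splines::bs(age, df = 5),
                      data = as.data.frame(adj))
  grid <- data.frame(age = seq(quantile(tab$age, 0.05),
                               quantile(tab$age, 0.95), length.out = 25))
  expect_equal(predict(sm_out, grid), predict(sm_in, grid),
               tolerance = 0.05)
})

test_that("EB shrinkage vanishes as site n grows", {
  dist_at_n <- function(n) {
    tab <- toy_table(2 * n, seed = 52, sites = c("a", "b"))
    model <- fit_combat_gam(tab, covariate_spec(character(0)),
                            metrics = c("ct_lh_bankssts", "sv_lh_thalamus"))
    mean(abs(model$gamma_star - model$gamma_hat))
  }
  d_small <- dist_at_n(15)
  d_big <- dist_at_n(400)
  expect_lt(d_big, d_small)
  expect_lt(d_big, 0.02)
})

test_that("fit/apply separation: held-out rows never touch the fit", {
  tab <- small_cohort()
  idx <- seq_len(nrow(tab)) %% 5 == 0
  train <- tab[!idx, , drop = FALSE]
  test <- tab[idx, , drop = FALSE]
  spec <- covariate_spec("age", c("bmi", "icv"), "group")
  m1 <- fit_combat_gam(train, spec)
  # corrupt the held-out rows completely; the fitted model cannot change
  test2 <- test
  mets <- intersect(table_manifest(tab)$metric, names(test2))
  for (v in setdiff(mets, c("icv"))) test2[[v]] <- test2[[v]] * 10 + 3
  m2 <- fit_combat_gam(train, spec)
  expect_identical(m1$gamma_star, m2$gamma_star)
  expect_identical(m1$beta_cov, m2$beta_cov)
  a1 <- apply_combat_gam(m1, test)
  expect_identical(nrow(a1), nrow(test))
})

test_that("unknown sites and empty tables behave per contract", {
  tab <- small_cohort()
  model <- fit_combat_gam(tab, covariate_spec("age"),
                          metrics = "ct_lh_bankssts")
  bad <- tab[1:4, , drop = FALSE]
  bad$site <- "elsewhere"
  expect_error(apply_combat_gam(model, bad), "unknown site")
  empty <- tab[integer(0), , drop = FALSE]
  expect_identical(nrow(apply_combat_gam(model, empty)), 0L)
})

test_that("missing cells are complete-case fitted and preserved", {
  tab <- apply_missingness(small_cohort(), 0.05, seed = 77)
  spec <- covariate_spec("age", retained_factors = "group")
  model <- fit_combat_gam(tab, spec)
  adj <- apply_combat_gam(model, tab)
  v <- "ct_lh_fusiform"
  expect_identical(is.na(adj[[v]]), is.na(tab[[v]]))
})

test_that("model JSON round-trip reproduces adjustments", {
  tab <- small_cohort()
  spec <- covariate_spec("age", c("bmi", "icv"), "group")
  model <- fit_combat_gam(tab, spec, metrics = c("ct_lh_bankssts",
                                                 "sa_rh_insula"))
  f <- tempfile(fileext = ".json")
  write_combat_model(model, f)
  model2 <- read_combat_model(f)
  a1 <- apply_combat_gam(model, tab)
  a2 <- apply_combat_gam(model2, tab)
  expect_equal(a2$ct_lh_bankssts, a1$ct_lh_bankssts, tolerance = 1e-12)
  unlink(f)
})

test_that("collinear covariates raise a design error", {
  tab <- toy_table(60, seed = 8, sites = c("a", "b"))
  tab$bmi <- 2 * tab$age  # exactly collinear
  expect_error(
    fit_combat_gam(tab, covariate_spec(character(0),
                                       linear_terms = c("age", "bmi")),
                   metrics = "ct_lh_bankssts"),
    "collinear")
})
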