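# Shared fixtures, built once per test run. Sizes are kept small; anything
# statistical uses fixed seeds so the suite is deterministic.

fix_env <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = fix_env, inherits = FALSE))
    assign(name, expr, envir = fix_env)
  get(name, envir = fix_env, inherits = FALSE)
}

small_cohort <- function() memo("small_cohort", {
  generate_cohort(small_cohort_config(n = 240, n_sites = 2, seed = 101))
})

reference_small <- function() memo("reference_small", {
  generate_reference(1200, seed = 202)
})

normative_small <- function() memo("normative_small", {
  fit_normative(reference_small())
})

# single-site, two-metric toy table built directly (not via the generator)
toy_table <- function(n = 60, seed = 7, sites = "s1") {
  set.seed(seed)
  n_s <- length(sites)
  man <- region_manifest()
  df <- data.frame(
    participant_id = sprintf("T%03d", seq_len(n)),
    site = rep(sites, each = ceiling(n / n_s))[seq_len(n)],
    group = rep(c("AN", "HC"), length.out = n),
    subtype = "none", age = runif(n, 12, 30), bmi = runif(n, 15, 25),
    icv = rnorm(n, 1.45e6, 1e5))
  df$subtype[df$group == "AN"] <- rep(c("AN-R", "AN-BP"),
                                      length.out = sum(df$group == "AN"))
  df$ct_lh_bankssts <- rnorm(n, 2.5, 0.15)
  df$sv_lh_thalamus <- rnorm(n, 7000, 700)
  as_morpho_table(df, man)
}

# fast classification config used across tests
fast_clf <- function(task = "AN_vs_HC", seed = 1, ...) {
  pipeline_config(task = task, pca_grid = c(10, 20), cost_grid = c(0.1, 1),
                  outer_folds = 5, inner_folds = 3, n_permutations = 99,
                  seed = seed, ...)
}
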