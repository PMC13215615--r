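#' Deterministic child seeds
#'
#' Every stochastic stage of the package derives its own seed from a single
#' top-level seed and a stage label, so that pipelines are reproducible
#' end-to-end while stages remain independently re-runnable.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # multiplicative string hash folded with the parent seed; kept < 2^31
  h <- 19349663
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so library internals never
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Multiplicative hash of a character scalar, as hex; config provenance only.
fnv1a_hex <- function(x) {
  h <- 19349663
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 4294967296
  sprintf("%08x", h)
}
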