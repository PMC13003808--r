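# Small fixture specs and data generators shared across the test files.
# Everything is built in code; no stored fixtures.

# Single latent with fixed unit loadings and unit variances:
# implied Sigma = [[2, 1], [1, 2]] by hand path-tracing.
two_indicator_fixed_spec <- function() {
  wm_model_spec(c("y1", "y2"), "f", rbind(
    pt_row("f", "=~", "y1", free = FALSE, value = 1),
    pt_row("f", "=~", "y2", free = FALSE, value = 1),
    pt_row("f", "~~", "f", free = FALSE, value = 1),
    pt_row("y1", "~~", "y1", free = FALSE, value = 1),
    pt_row("y2", "~~", "y2", free = FALSE, value = 1)))
}

# Free single-factor model with k indicators (variance-1 identification).
single_factor_spec <- function(k = 5, observed = paste0("y", seq_len(k))) {
  rows <- rbind(
    do.call(rbind, lapply(observed, function(v) pt_row("f", "=~", v))),
    pt_row("f", "~~", "f", free = FALSE, value = 1),
    do.call(rbind, lapply(observed, function(v) pt_row(v, "~~", v))),
    do.call(rbind, lapply(observed, function(v)
      pt_row(v, "~1", v, free = TRUE, value = 0))))
  wm_model_spec(observed, "f", rows)
}

# Saturated (unstructured) spec over p variables.
saturated_spec <- function(observed) {
  p <- length(observed)
  rows <- do.call(rbind, c(
    lapply(observed, function(v) pt_row(v, "~~", v)),
    if (p > 1) {
      cmb <- utils::combn(observed, 2L)
      lapply(seq_len(ncol(cmb)), function(i)
        pt_row(cmb[1, i], "~~", cmb[2, i], value = 0.1))
    },
    lapply(observed, function(v) pt_row(v, "~1", v, free = TRUE, value = 0))))
  wm_model_spec(observed, character(), rows)
}

# MVN draws with given moments (chol-based, deterministic under seed).
rmvn <- function(n, mu, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- chol(Sigma)
  Y <- sweep(matrix(stats::rnorm(n * length(mu)), n) %*% R, 2L, mu, `+`)
  colnames(Y) <- names(mu) %||% paste0("y", seq_along(mu))
  as.data.frame(Y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct multivariate normal log-density, independent of the package's
# pattern-based implementation (used as oracle for complete data).
direct_mvn_loglik <- function(Y, mu, Sigma) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  Si <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  s <- 0
  for (i in seq_len(nrow(Y))) {
    d <- Y[i, ] - mu
    s <- s - 0.5 * (p * log(2 * pi) + ld + drop(d %*% Si %*% d))
  }
  as.numeric(s)
}

# Small two-site cohort used by pipeline tests (kept light on purpose).
small_cohort <- function(seed = 42, nA = 80, nB = 90, mriB = 80) {
  generate_cohort(wm_synthetic_config(
    n_per_site = c(A = nA, B = nB), mri_subset = c(A = nA, B = mriB),
    seed = seed))
}
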