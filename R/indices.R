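#' Goodness-of-fit indices
#'
#' Computes the conventional incremental and absolute fit indices from a
#' fitted model and the independence (baseline) model estimated on the same
#' data and missingness:
#'
#' * `CFI  = 1 - max(chi2_M - df_M, 0) / max(chi2_B - df_B, chi2_M - df_M, 0)`
#' * `TLI  = ((chi2_B/df_B) - (chi2_M/df_M)) / ((chi2_B/df_B) - 1)` (not clipped)
#' * `RMSEA = sqrt(max(chi2_M - df_M, 0) / (df_M * (n - 1)))`
#' * `SRMR` = root mean square of the standardized residuals between the
#'   saturated ("sample") covariance and the model-implied covariance, over
#'   the lower triangle including the diagonal.
#'
#' Conventional thresholds: CFI/TLI >= .90 and RMSEA/SRMR <= .08 acceptable;
#' >= .95 / <= .05 good.
#'
#' @param fit a `wm_fit`.
#' @param baseline result of the internal independence fit; computed from
#'   `fit$data` when omitted.
#' @param n sample size; defaults to `fit$n_used`.
#' @return tibble with `chi2`, `df`, `p_value`, `chi2_baseline`,
#'   `df_baseline`, `cfi`, `tli`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(fit, baseline = NULL, n = fit$n_used) {
  if (is.null(baseline)) baseline <- fit_independence(fit$data)
  chi2_b <- max(0, 2 * (fit$loglik_sat - baseline$loglik))
  out <- fit_index_values(fit$chi2, fit$df, chi2_b, baseline$df, n)
  out$srmr <- srmr_value(fit$sat_Sigma, fit$Sigma_hat)
  out
}

#' @rdname fit_indices
#' @param chi2,df model test statistic and degrees of freedom.
#' @param chi2_baseline,df_baseline the same for the independence model.
#' @export
fit_index_values <- function(chi2, df, chi2_baseline, df_baseline, n) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli <- if (df > 0 && df_baseline > 0 && (chi2_baseline / df_baseline) != 1)
    ((chi2_baseline / df_baseline) - (chi2 / df)) /
      ((chi2_baseline / df_baseline) - 1) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_
  tibble::tibble(
    chi2 = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
              else NA_real_,
    chi2_baseline = chi2_baseline, df_baseline = df_baseline,
    cfi = cfi, tli = tli, rmsea = rmsea, srmr = NA_real_)
}

# Standardized residual RMS; S plays the role of the sample covariance
# (under missing data, the saturated FIML estimate).
srmr_value <- function(S, Sigma) {
  d <- sqrt(diag(S))
  R <- (S - Sigma) / tcrossprod(d)
  sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
}

#' Akaike weights
#'
#' Transforms AIC values into model weights
#' `w_i = exp(-(AIC_i - min AIC)/2) / sum_j exp(-(AIC_j - min AIC)/2)`,
#' interpretable as conditional model probabilities over the candidate set.
#' The min-AIC shift keeps the exponentials numerically stable.
#'
#' @param aic numeric vector of AIC values (`NA` allowed; propagated).
#' @return numeric vector of weights summing to 1 over the non-`NA` entries.
#' @export
akaike_weights <- function(aic) {
  if (!length(aic) || all(is.na(aic))) stop("no finite AIC values")
  d <- aic - min(aic, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Compare fitted models by AIC
#'
#' Builds the comparison table over a candidate set: AIC (`-2 loglik + 2 q`),
#' AIC differences, Akaike weights over the *admissible* models only, and fit
#' indices. Inadmissible models (non-convergence or non-positive-definite
#' parameter/latent covariance matrices) are retained in the table with their
#' verdict but excluded from the weights — never silently dropped.
#'
#' @param fits named list of `wm_fit` objects fitted to the same data.
#' @return tibble of class `wm_comparison`, one row per model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    v <- check_validity(f)
    ix <- fit_indices(f)
    tibble::tibble(model = nm, n = f$n_used,
                   q = n_free_params(f$spec),
                   aic = -2 * f$loglik + 2 * n_free_params(f$spec),
                   chi2 = ix$chi2, df = ix$df, p_value = ix$p_value,
                   cfi = ix$cfi, tli = ix$tli, rmsea = ix$rmsea,
                   srmr = ix$srmr, converged = f$converged,
                   admissible = v$admissible,
                   reasons = paste(v$reasons, collapse = "; "))
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aic <- NA_real_
  out$weight <- NA_real_
  adm <- out$admissible
  if (any(adm)) {
    out$delta_aic[adm] <- out$aic[adm] - min(out$aic[adm])
    out$weight[adm] <- akaike_weights(out$aic[adm])
  }
  class(out) <- c("wm_comparison", class(out))
  out
}

#' Select the winning model(s)
#'
#' The model with the maximal Akaike weight wins; models whose weight is
#' within `tie_tol` of the maximum are reported as joint winners (mirroring
#' a 0.50/0.50 tie between two architectures).
#'
#' @param comparison a `wm_comparison` from [compare_models()].
#' @param tie_tol weight difference below which models tie (default 0.005).
#' @return character vector of winning model names.
#' @export
select_model <- function(comparison, tie_tol = 0.005) {
  adm <- comparison[comparison$admissible & !is.na(comparison$weight), ]
  if (!nrow(adm)) stop("no admissible model in the comparison")
  wmax <- max(adm$weight)
  adm$model[adm$weight > wmax - tie_tol]
}

#' Power to detect model misfit via the RMSEA
#'
#' Power of the likelihood-ratio test of exact fit when the population misfit
#' corresponds to `epsilon_alt`: the critical value is the upper-`alpha`
#' quantile of the central chi-square with `df` degrees of freedom, the
#' alternative is noncentral chi-square with noncentrality
#' `lambda = (n - 1) * df * epsilon_alt^2`.
#'
#' @param n sample size (>= 2).
#' @param df model degrees of freedom (>= 1).
#' @param alpha test level in (0, 1).
#' @param epsilon_alt population RMSEA under the alternative (>= 0).
#' @return power (scalar in \[alpha, 1\]).
#' @export
power_rmsea <- function(n, df, alpha = 0.05, epsilon_alt = 0.05) {
  stopifnot(n >= 2, df >= 1, alpha > 0, alpha < 1, epsilon_alt >= 0)
  crit <- stats::qchisq(1 - alpha, df)
  lambda <- (n - 1) * df * epsilon_alt^2
  stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE)
}
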