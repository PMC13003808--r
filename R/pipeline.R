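#' Assemble analysis-ready data from a cohort
#'
#' Runs the fixed preprocessing chain per marker (outlier removal, cluster
#' averaging, within-then-across z-standardization), scores and standardizes
#' the intelligence halves the same way, codes the data-source dummy
#' (A = 0, B = 1) and residualizes age on source.
#'
#' @param cohort a [generate_cohort()] result, or an equivalent list with
#'   `tracts` (per-marker tables), `items` and `demographics`.
#' @param map cluster map for tract averaging.
#' @return list with `clusters` (standardized per-marker tibbles),
#'   `intelligence` (standardized odd/even halves), `demographics` (with
#'   `source` and `age_resid`), `removal_reports`, `excluded_subjects`.
#' @export
prepare_analysis_data <- function(cohort, map = default_cluster_map()) {
  clusters <- list(); reports <- list()
  for (m in names(cohort$tracts)) {
    pp <- preprocess_marker_table(cohort$tracts[[m]], map = map)
    clusters[[m]] <- pp$table
    reports[[m]] <- pp$report
  }
  sc <- score_and_filter_intelligence(cohort$items)
  demo <- cohort$demographics
  gf <- dplyr::inner_join(sc$scores, demo[, c("subject_id", "site")],
                          by = "subject_id")
  gf <- zstandardize_within_then_across(
    gf[, c("subject_id", "site", "gf_odd", "gf_even")])
  demo$source <- as.numeric(demo$site == "B")
  demo$age_resid <- residualize_age(demo$age, demo$site)
  # unit-variance covariate keeps the information matrix well conditioned;
  # age slopes are then per SD of (source-residualized) age
  sd_age <- stats::sd(demo$age_resid)
  if (sd_age > 0) demo$age_resid <- demo$age_resid / sd_age
  list(clusters = clusters, intelligence = gf, demographics = demo,
       removal_reports = reports, excluded_subjects = sc$excluded)
}

marker_fit_table <- function(data, marker, age_control = FALSE) {
  tbl <- data$clusters[[marker]]
  demo <- data$demographics[, c("subject_id", "source", "age_resid")]
  tbl <- dplyr::left_join(tbl, demo, by = "subject_id")
  use_source <- length(unique(tbl$site)) > 1L
  keep <- c(wm_indicators(), if (use_source) "source",
            if (age_control) "age_resid")
  list(table = tbl[, keep, drop = FALSE], use_source = use_source)
}

#' Marker-wise systematic model comparison
#'
#' Fits the competing measurement architectures per marker with FIML on the
#' standardized cluster indicators (plus the data-source dummy where a
#' marker spans both sites; a marker acquired at one site only — MTR — is
#' compared within that site without the dummy), applies the
#' negative-variance rule and the admissibility checks, and ranks admissible
#' models by Akaike weight.
#'
#' @param data a [prepare_analysis_data()] result.
#' @param markers markers to compare.
#' @param models architecture names (default: all twelve).
#' @param age_control regress all latents on residualized age?
#' @param restarts jittered optimizer restarts per fit (passed to
#'   [fit_wm_model()]).
#' @param seed RNG seed (restart jitter).
#' @param negative_variance_rule apply [apply_negative_variance_rule()]?
#' @return named list per marker: `comparison` (a `wm_comparison`),
#'   `winners`, `fits`.
#' @export
run_marker_comparison <- function(data, markers = names(data$clusters),
                                  models = wm_model_names(),
                                  age_control = FALSE, restarts = 2L,
                                  seed = 1L,
                                  negative_variance_rule = TRUE) {
  set.seed(seed)
  out <- list()
  for (m in markers) {
    ft <- marker_fit_table(data, m, age_control)
    fits <- list()
    for (mod in models) {
      spec <- build_measurement_model(mod, source_dummy = ft$use_source,
                                      age = age_control)
      fit <- fit_wm_model(spec, ft$table, variance_scale = "raw",
                          restarts = restarts)
      if (negative_variance_rule && nrow(fit$heywood)) {
        fit <- apply_negative_variance_rule(fit, restarts = restarts)$fit
      }
      fits[[mod]] <- fit
    }
    comparison <- compare_models(fits)
    if (!any(comparison$admissible))
      stop("all models inadmissible for marker ", m)
    out[[m]] <- list(comparison = comparison,
                     winners = select_model(comparison), fits = fits)
  }
  out
}

#' Merge standardized marker, intelligence and covariate data for joint models
#'
#' Full join over subjects: marker columns are prefixed `<marker>_`, missing
#' markers/subjects stay `NA` (missing by design, handled by FIML).
#'
#' @param data a [prepare_analysis_data()] result.
#' @param markers markers to include.
#' @return tibble keyed by `subject_id`.
#' @export
joint_fit_table <- function(data, markers = names(data$clusters)) {
  demo <- data$demographics[, c("subject_id", "source", "age_resid")]
  out <- demo
  for (m in markers) {
    tbl <- data$clusters[[m]][, c("subject_id", wm_indicators())]
    names(tbl)[-1] <- paste0(m, "_", names(tbl)[-1])
    out <- dplyr::left_join(out, tbl, by = "subject_id")
  }
  out <- dplyr::left_join(
    out, data$intelligence[, c("subject_id", "gf_odd", "gf_even")],
    by = "subject_id")
  out
}

#' Joint multi-marker model and the latent regression of fluid intelligence
#'
#' Fits the joint white matter models (correlated general factors vs a
#' higher-order factor, optionally each with the five orthogonal method
#' factors), drops solutions whose parameter or latent covariance matrix is
#' not positive definite, selects the winner by Akaike weight, then adds the
#' latent fluid-intelligence outcome regressed on the marker general factors
#' and reports standardized coefficients with 95% confidence intervals and
#' the latent correlations among the general factors.
#'
#' @param data a [prepare_analysis_data()] result.
#' @param architecture measurement architecture (single name or named per
#'   marker).
#' @param markers markers entering the joint model.
#' @param variants joint structures to compare.
#' @param method_factors also try the method-factor variants?
#' @param age_control regress all latents on residualized age?
#' @param restarts,seed optimizer controls.
#' @return list with `comparison`, `winner`, `fit` (the final model with
#'   intelligence), `betas`, `latent_cor`.
#' @export
run_joint_and_intelligence <- function(data,
                                       architecture = "bilateral_clustered_hemisphere_bifactor",
                                       markers = names(data$clusters),
                                       variants = c("correlated", "hierarchical"),
                                       method_factors = FALSE,
                                       age_control = FALSE, restarts = 1L,
                                       seed = 1L) {
  set.seed(seed)
  tbl <- joint_fit_table(data, markers)
  single_site <- markers[vapply(markers, function(m)
    length(unique(data$clusters[[m]]$site)) < 2L, logical(1))]
  cand <- list()
  for (v in variants) {
    cand[[v]] <- build_joint_model(architecture, markers = markers, mode = v,
                                   source_dummy = TRUE, age = age_control,
                                   single_site_markers = single_site)
    if (method_factors)
      cand[[paste0(v, "_method")]] <-
        build_joint_model(architecture, markers = markers, mode = v,
                          method_factors = TRUE, source_dummy = TRUE,
                          age = age_control, single_site_markers = single_site)
  }
  fits <- lapply(cand, fit_wm_model, data = tbl, variance_scale = "raw",
                 restarts = restarts)
  comparison <- compare_models(fits)
  winner <- select_model(comparison)[1]
  winner_mode <- if (grepl("^hier", winner)) "hierarchical" else "correlated"
  final_spec <- build_joint_model(architecture, markers = markers,
                                  mode = winner_mode,
                                  method_factors = grepl("method", winner),
                                  intelligence = TRUE, source_dummy = TRUE,
                                  age = age_control,
                                  single_site_markers = single_site)
  fit <- fit_wm_model(final_spec, tbl, variance_scale = "raw",
                      restarts = restarts)
  if (nrow(fit$heywood)) {
    fit <- apply_negative_variance_rule(fit, restarts = restarts)$fit
  }
  gs <- paste0("g", markers)
  list(comparison = comparison, winner = winner, fit = fit,
       betas = structural_coefficients(fit, outcome = "gFluid",
                                       predictors = gs),
       latent_cor = latent_correlations(fit, gs))
}

#' Standardized structural coefficients
#'
#' Extracts the regressions of `outcome` on `predictors`, standardized by
#' the model-implied latent standard deviations; confidence bounds are the
#' raw Wald bounds rescaled by the same factor.
#'
#' @param fit a `wm_fit`.
#' @param outcome,predictors latent variable names.
#' @return tibble with raw and standardized estimates, 95% CI and p-values.
#' @export
structural_coefficients <- function(fit, outcome = "gFluid",
                                    predictors = NULL) {
  pt <- fit$spec$ptable
  ix <- which(pt$op == "~" & pt$lhs == outcome &
                (if (is.null(predictors)) TRUE else pt$rhs %in% predictors))
  sds <- sqrt(pmax(diag(fit$Sigma_all), 0))
  rows <- lapply(ix, function(i) {
    lab <- pt$label[i]
    est <- fit$theta[[lab]]
    se <- fit$se[[lab]]
    ratio <- sds[pt$rhs[i]] / sds[outcome]
    tibble::tibble(outcome = outcome, predictor = pt$rhs[i],
                   beta = est, se = se,
                   beta_std = est * ratio,
                   ci_lower_std = (est - 1.959964 * se) * ratio,
                   ci_upper_std = (est + 1.959964 * se) * ratio,
                   p_value = 2 * stats::pnorm(-abs(est / se)))
  })
  dplyr::bind_rows(rows)
}

#' Model-implied latent correlations
#'
#' @param fit a `wm_fit`.
#' @param latents latent names (default: all).
#' @return correlation matrix.
#' @export
latent_correlations <- function(fit, latents = fit$spec$latents) {
  V <- fit$Sigma_all[latents, latents, drop = FALSE]
  stats::cov2cor(V)
}

#' Age-controlled replication of the full analysis
#'
#' Repeats the marker-wise model comparison and the joint/intelligence stage
#' with residualized age regressing on every latent variable, and reports
#' the age-free and age-controlled structural coefficients side by side.
#'
#' @param data a [prepare_analysis_data()] result.
#' @param age_free optional previously computed
#'   [run_joint_and_intelligence()] result without age control (recomputed
#'   when `NULL`).
#' @param markers,models,architecture,restarts,seed as in the stage
#'   functions.
#' @param compare_models_per_marker rerun the full marker comparison? (the
#'   expensive part; skipped when `FALSE`).
#' @return list with `marker_comparison` (or `NULL`), `joint`, and `betas`
#'   combining both runs.
#' @export
run_age_controlled <- function(data, age_free = NULL,
                               markers = names(data$clusters),
                               models = wm_model_names(),
                               architecture = "bilateral_clustered_hemisphere_bifactor",
                               restarts = 1L, seed = 1L,
                               compare_models_per_marker = TRUE) {
  if (stats::var(data$demographics$age) == 0) {
    warning("age is constant; the age-controlled run equals the age-free run")
    return(list(marker_comparison = NULL,
                joint = age_free, betas = if (!is.null(age_free)) age_free$betas))
  }
  mc <- if (compare_models_per_marker)
    run_marker_comparison(data, markers = markers, models = models,
                          age_control = TRUE, restarts = restarts, seed = seed)
  if (is.null(age_free))
    age_free <- run_joint_and_intelligence(data, architecture = architecture,
                                           markers = markers,
                                           restarts = restarts, seed = seed)
  joint_age <- run_joint_and_intelligence(data, architecture = architecture,
                                          markers = markers,
                                          age_control = TRUE,
                                          restarts = restarts, seed = seed)
  betas <- dplyr::bind_rows(
    dplyr::mutate(age_free$betas, analysis = "age_free"),
    dplyr::mutate(joint_age$betas, analysis = "age_controlled"))
  list(marker_comparison = mc, joint = joint_age, age_free = age_free,
       betas = betas)
}

#' Serialize a fit to JSON
#'
#' @param fit a `wm_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  v <- check_validity(fit)
  obj <- list(estimates = as.list(fit$theta), se = as.list(fit$se),
              loglik = fit$loglik, loglik_sat = fit$loglik_sat,
              chi2 = fit$chi2, df = fit$df, n = fit$n_used,
              converged = fit$converged, admissible = v$admissible,
              reasons = v$reasons,
              heywood = fit$heywood, standardized = fit$standardized)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
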