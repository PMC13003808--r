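#' True population parameters for cohort generation
#'
#' Defaults encode mid-range standardized loadings (general factor 0.6 on the
#' bilateral cluster latents, 0.7 cluster-to-indicator, 0.4 hemisphere
#' bifactor) with residual variances chosen so all latent and indicator
#' variances equal 1 before site/age effects; the cross-marker general-factor
#' correlations and the structural coefficients of fluid intelligence use the
#' estimates printed for the real cohort (r(gFA,gINVF) = .03,
#' r(gFA,gMTR) = -.11, r(gINVF,gMTR) = .46; beta = 0.26 / -0.05 / 0.25 for
#' FA / INVF / MTR). Age enters every latent linearly.
#'
#' @param loading_g,loading_cluster,loading_hem standardized loadings.
#' @param marker_cor 3x3 correlation matrix of the marker general factors
#'   (order FA, INVF, MTR).
#' @param beta_gf structural coefficients of fluid intelligence on the
#'   marker general factors (named FA/INVF/MTR).
#' @param age_slope_marker,age_slope_gf change in the latent per year of
#'   (centered) age.
#' @param tract_noise_sd SD of tract-level noise around the cluster
#'   indicator.
#' @param item_discrimination range of 2PL discriminations.
#' @param item_difficulty named list of 2PL difficulty ranges per site.
#' @return list of class `wm_true_params`.
#' @export
wm_true_params <- function(loading_g = 0.6, loading_cluster = 0.7,
                           loading_hem = 0.4,
                           marker_cor = matrix(c(1, .03, -.11,
                                                 .03, 1, .46,
                                                 -.11, .46, 1), 3, 3,
                                               dimnames = list(c("FA", "INVF", "MTR"),
                                                               c("FA", "INVF", "MTR"))),
                           beta_gf = c(FA = 0.26, INVF = -0.05, MTR = 0.25),
                           age_slope_marker = -0.02, age_slope_gf = -0.015,
                           tract_noise_sd = 0.3,
                           item_discrimination = c(0.8, 2),
                           item_difficulty = list(A = c(-2, 1), B = c(-1.5, 1.5))) {
  tp <- list(loading_g = loading_g, loading_cluster = loading_cluster,
             loading_hem = loading_hem, marker_cor = marker_cor,
             beta_gf = beta_gf, age_slope_marker = age_slope_marker,
             age_slope_gf = age_slope_gf, tract_noise_sd = tract_noise_sd,
             item_discrimination = item_discrimination,
             item_difficulty = item_difficulty)
  tp$resid_cluster <- 1 - loading_g^2
  tp$resid_ind <- 1 - loading_cluster^2 - loading_hem^2
  ev <- eigen(marker_cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("configuration error: marker general-factor correlation matrix ",
         "is not positive definite")
  expl <- drop(t(beta_gf) %*% marker_cor %*% beta_gf)
  if (expl >= 1)
    stop("configuration error: structural coefficients imply non-positive ",
         "residual variance for gFluid")
  tp$resid_gf <- 1 - expl
  if (tp$resid_cluster <= 0)
    stop("configuration error: general-factor loading implies non-positive ",
         "bilateral-cluster residual variance")
  if (tp$resid_ind <= 0)
    stop("configuration error: cluster/hemisphere loadings imply ",
         "non-positive indicator residual variance")
  class(tp) <- "wm_true_params"
  tp
}

#' Configuration of the synthetic two-site cohort
#'
#' Defaults emulate the study design: site A with 150 participants aged
#' 20-74, all three markers and a 48-item / 5-option matrix test; site B
#' with 215 participants aged 18-40, MRI for 200 of them, FA and INVF only
#' (no MTR acquisition), and a 36-item / 8-option untimed test. Site effects
#' are additive mean shifts on the standardized indicators; a small fraction
#' of tract cells can be replaced by +-4 SD extremes to exercise outlier
#' screening. The seed fully determines the cohort.
#'
#' @param n_per_site named counts (`A`, `B`).
#' @param age_range named list of (min, max) ages in years.
#' @param mri_subset named counts of subjects with MRI per site.
#' @param markers_per_site named list of marker sets.
#' @param items_per_site,options_per_site test form description per site.
#' @param site_shift additive mean offset (in SD units) applied to site B
#'   indicators.
#' @param marker_scale raw-scale mean/SD per marker (FA and INVF unitless in
#'   \[0, 1\], MTR in percent); placeholders, since tract-level means are
#'   study-specific and are standardized away downstream.
#' @param outlier_rate fraction of tract cells replaced by extremes (0
#'   disables).
#' @param outlier_sd magnitude of injected extremes, in site-SD units.
#' @param true_params a [wm_true_params()].
#' @param seed integer seed.
#' @return list of class `wm_synthetic_config`.
#' @export
wm_synthetic_config <- function(n_per_site = c(A = 150, B = 215),
                                age_range = list(A = c(20, 74), B = c(18, 40)),
                                mri_subset = c(A = 150, B = 200),
                                markers_per_site = list(A = c("FA", "INVF", "MTR"),
                                                        B = c("FA", "INVF")),
                                items_per_site = c(A = 48, B = 36),
                                options_per_site = c(A = 5, B = 8),
                                site_shift = 0.3,
                                marker_scale = list(FA = c(mean = 0.45, sd = 0.08),
                                                    INVF = c(mean = 0.55, sd = 0.08),
                                                    MTR = c(mean = 35, sd = 3)),
                                outlier_rate = 0.005, outlier_sd = 4,
                                true_params = wm_true_params(), seed = 1L) {
  stopifnot(all(n_per_site > 0), all(mri_subset <= n_per_site),
            all(mri_subset >= 0), outlier_rate >= 0, outlier_rate < 1)
  structure(list(n_per_site = n_per_site, age_range = age_range,
                 mri_subset = mri_subset, markers_per_site = markers_per_site,
                 items_per_site = items_per_site,
                 options_per_site = options_per_site,
                 site_shift = site_shift, marker_scale = marker_scale,
                 outlier_rate = outlier_rate, outlier_sd = outlier_sd,
                 true_params = true_params, seed = as.integer(seed)),
            class = "wm_synthetic_config")
}

#' Generate a synthetic two-site cohort
#'
#' Draws subject latents from the configured true model (marker general
#' factors with the configured cross-marker correlations, bilateral cluster
#' latents, orthogonal hemisphere factors, a fluid-intelligence latent
#' regressed on the marker general factors, and linear age effects), builds
#' cluster-level indicators and tract-level values per marker on plausible
#' raw scales, applies the by-design missingness (MTR at site A only, MRI
#' for a subset of site B), and draws item responses from a
#' two-parameter-logistic model with guessing floor `1/n_options` driven by
#' the latent fluid-intelligence score.
#'
#' @param config a [wm_synthetic_config()].
#' @return list with `tracts` (per-marker tibbles, 52 tract columns),
#'   `clusters` (per-marker tibbles, 10 cluster columns), `demographics`,
#'   `items` (long), `latents` (true scores, for recovery checks), and
#'   `config`.
#' @export
generate_cohort <- function(config = wm_synthetic_config()) {
  stopifnot(inherits(config, "wm_synthetic_config"))
  tp <- config$true_params
  set.seed(config$seed)
  sites <- names(config$n_per_site)
  demo <- dplyr::bind_rows(lapply(sites, function(s) {
    n <- config$n_per_site[[s]]
    tibble::tibble(
      subject_id = sprintf("%s%04d", s, seq_len(n)),
      site = s,
      age = stats::runif(n, config$age_range[[s]][1], config$age_range[[s]][2]),
      has_mri = seq_len(n) <= config$mri_subset[[s]])
  }))
  n <- nrow(demo)
  a <- demo$age - 45  # fixed centering constant, common to both sites

  markers <- c("FA", "INVF", "MTR")
  Phi <- tp$marker_cor[markers, markers]
  U <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Phi)
  colnames(U) <- markers
  G <- U + tp$age_slope_marker * a  # marker general factors
  beta <- tp$beta_gf[markers]
  gfluid <- tp$age_slope_gf * a + drop(U %*% beta) +
    stats::rnorm(n, 0, sqrt(tp$resid_gf))

  cl <- wm_clusters()
  map <- default_cluster_map()
  clusters <- list(); tracts <- list()
  for (m in markers) {
    hem <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("L", "R")))
    Z <- matrix(NA_real_, n, 10, dimnames = list(NULL, wm_indicators()))
    for (c in cl) {
      lat <- tp$loading_g * G[, m] +
        stats::rnorm(n, 0, sqrt(tp$resid_cluster))
      for (h in c("L", "R")) {
        Z[, paste0(c, "_", h)] <- tp$loading_cluster * lat +
          tp$loading_hem * hem[, h] +
          stats::rnorm(n, 0, sqrt(tp$resid_ind))
      }
    }
    Z <- Z + config$site_shift * (demo$site == "B")
    sc <- config$marker_scale[[m]]
    avail <- demo$has_mri &
      vapply(demo$site, function(s) m %in% config$markers_per_site[[s]],
             logical(1))
    Zm <- Z[avail, , drop = FALSE]
    clusters[[m]] <- tibble::tibble(subject_id = demo$subject_id[avail],
                                    site = demo$site[avail]) |>
      dplyr::bind_cols(tibble::as_tibble(sc[["mean"]] + sc[["sd"]] * Zm))
    Tm <- matrix(NA_real_, sum(avail), nrow(map),
                 dimnames = list(NULL, map$tract))
    for (j in seq_len(nrow(map))) {
      ind <- paste0(map$cluster[j], "_", map$hemisphere[j])
      Tm[, j] <- Zm[, ind] + stats::rnorm(sum(avail), 0, tp$tract_noise_sd)
    }
    Tm <- sc[["mean"]] + sc[["sd"]] * Tm
    if (config$outlier_rate > 0) Tm <- inject_outliers(
      Tm, demo$site[avail], config$outlier_rate, config$outlier_sd)
    tracts[[m]] <- tibble::tibble(subject_id = demo$subject_id[avail],
                                  site = demo$site[avail]) |>
      dplyr::bind_cols(tibble::as_tibble(Tm))
  }

  items <- dplyr::bind_rows(lapply(sites, function(s) {
    k <- config$items_per_site[[s]]
    guess <- 1 / config$options_per_site[[s]]
    disc <- stats::runif(k, tp$item_discrimination[1], tp$item_discrimination[2])
    diff <- stats::runif(k, tp$item_difficulty[[s]][1], tp$item_difficulty[[s]][2])
    ix <- which(demo$site == s)
    th <- gfluid[ix]
    pr <- guess + (1 - guess) *
      stats::plogis(outer(th, seq_len(k), function(t, j) disc[j] * (t - diff[j])))
    tibble::tibble(
      subject_id = rep(demo$subject_id[ix], each = k),
      site = s,
      item = rep(seq_len(k), times = length(ix)),
      n_items = k, n_options = config$options_per_site[[s]],
      correct = as.integer(stats::runif(length(ix) * k) < as.vector(t(pr))))
  }))

  latents <- tibble::tibble(subject_id = demo$subject_id, site = demo$site,
                            gFA = G[, "FA"], gINVF = G[, "INVF"],
                            gMTR = G[, "MTR"], gFluid = gfluid,
                            uFA = U[, "FA"], uINVF = U[, "INVF"],
                            uMTR = U[, "MTR"])
  list(tracts = tracts, clusters = clusters,
       demographics = demo[, c("subject_id", "site", "age", "has_mri")],
       items = items, latents = latents, config = config)
}

# Replace a random fraction of cells with site-mean +- k * site-SD extremes.
inject_outliers <- function(M, site, rate, k) {
  for (s in unique(site)) {
    rows <- which(site == s)
    cells <- which(stats::runif(length(rows) * ncol(M)) < rate)
    if (!length(cells)) next
    mu <- colMeans(M[rows, , drop = FALSE])
    sd <- apply(M[rows, , drop = FALSE], 2, stats::sd)
    for (cell in cells) {
      i <- rows[(cell - 1L) %% length(rows) + 1L]
      j <- (cell - 1L) %/% length(rows) + 1L
      M[i, j] <- mu[j] + sample(c(-1, 1), 1L) * k * sd[j]
    }
  }
  M
}

#' Simulate data from an arbitrary model specification
#'
#' I.i.d. multivariate normal draws with the model-implied moments at
#' `theta`; deterministic under `seed`.
#'
#' @param spec a [wm_model_spec()].
#' @param theta free-parameter vector (canonical order).
#' @param n number of rows.
#' @param seed integer seed.
#' @return tibble of observed variables.
#' @export
simulate_from_spec <- function(spec, theta = default_theta(spec), n, seed = 1L) {
  mom <- implied_moments(spec, theta)
  R <- tryCatch(chol(mom$Sigma), error = function(e)
    stop("implied covariance is not positive definite"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  Y <- sweep(Z %*% R, 2L, mom$mu, `+`)
  colnames(Y) <- spec$observed
  tibble::as_tibble(Y)
}

#' Write a synthetic cohort to disk
#'
#' One CSV per marker for tract- and cluster-level tables, plus
#' `demographics.csv`, `items.csv`, and the configuration as YAML (seed
#' included).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(cohort$tracts)) {
    utils::write.csv(cohort$tracts[[m]],
                     file.path(dir, paste0("tracts_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cohort$clusters[[m]],
                     file.path(dir, paste0("clusters_", m, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$items, file.path(dir, "items.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$true_params <- unclass(cfg$true_params)
  cfg$true_params$marker_cor <- as.vector(cfg$true_params$marker_cor)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' True parameter vector in the metric of a measurement architecture
#'
#' Expresses the generator's population values in the parameterization used
#' by the fitted models, where endogenous bilateral cluster latents have
#' residual variance fixed to 1: with true cluster residual variance
#' `1 - loading_g^2` the equivalent loadings are `loading_g / s` into the
#' cluster latents and `loading_cluster * s` onto the indicators, with
#' `s = sqrt(1 - loading_g^2)`. Supports the hemisphere-bifactor bilateral
#' architecture used as the generator truth.
#'
#' @param spec the [build_measurement_model()] spec (no covariates), e.g.
#'   `"BiClusHem-BiF"`.
#' @param tp a [wm_true_params()].
#' @return named theta vector for [implied_moments()] /
#'   [simulate_from_spec()].
#' @export
true_theta_bilateral_hem <- function(spec, tp = wm_true_params()) {
  pt <- spec$ptable
  s <- sqrt(1 - tp$loading_g^2)
  th <- default_theta(spec)
  lab <- function(sel) unique(pt$label[sel & pt$free])
  th[lab(pt$op == "=~" & grepl("^g", pt$lhs))] <- tp$loading_g / s
  th[lab(pt$op == "=~" & grepl("bl_", pt$lhs))] <- tp$loading_cluster * s
  th[lab(pt$op == "=~" & grepl("hem_", pt$lhs))] <- tp$loading_hem
  th[lab(pt$op == "~~" & pt$lhs == pt$rhs & pt$lhs %in% spec$observed)] <-
    tp$resid_ind
  th[lab(pt$op == "~1")] <- 0
  th
}
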