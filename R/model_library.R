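#' Functional tract clusters of the HCP-1065 atlas
#'
#' The 52 association and projection tracts (26 per hemisphere, `_L`/`_R`
#' suffixes) grouped into five bilateral functional systems:
#'
#' * cingulum (6/hemisphere): the five cingulum segments plus SLF1,
#' * posterior ventral (2/hemisphere): uncinate and inferior fronto-occipital
#'   fasciculus,
#' * anterior ventral (4/hemisphere): middle longitudinal fasciculus,
#'   temporoparietal aslant tract, vertical occipital fasciculus, inferior
#'   longitudinal fasciculus,
#' * arcuate (4/hemisphere): frontal aslant tract, SLF2, SLF3, arcuate
#'   fasciculus,
#' * projection (10/hemisphere): the remaining projection fibers of the
#'   atlas (corticostriatal and thalamic radiations, optic radiation,
#'   corticospinal and corticobulbar tracts, fornix).
#'
#' @return tibble with columns `tract`, `cluster`, `hemisphere` (52 rows).
#' @export
default_cluster_map <- function() {
  members <- list(
    cingulum = c("CG_frontal_parahippocampal", "CG_frontal_parietal",
                 "CG_parahippocampal", "CG_parahippocampal_parietal",
                 "CG_parolfactory", "SLF1"),
    posterior_ventral = c("UF", "IFOF"),
    anterior_ventral = c("MdLF", "TPAT", "VOF", "ILF"),
    arcuate = c("FAT", "SLF2", "SLF3", "AF"),
    projection = c("CS_anterior", "CS_posterior", "CS_superior",
                   "TR_anterior", "TR_posterior", "TR_superior",
                   "OR", "CST", "CBT", "FX"))
  rows <- lapply(names(members), function(cl) {
    tibble::tibble(
      tract = c(paste0(members[[cl]], "_L"), paste0(members[[cl]], "_R")),
      cluster = cl,
      hemisphere = rep(c("L", "R"), each = length(members[[cl]])))
  })
  dplyr::bind_rows(rows)
}

#' Functional cluster and indicator names
#'
#' `wm_clusters()` returns the five bilateral functional systems;
#' `wm_indicators()` the ten cluster-by-hemisphere indicator names, in model
#' order, optionally prefixed (e.g. `"FA_"` in joint models).
#'
#' @param prefix optional marker prefix for the indicator names.
#' @export
wm_clusters <- function() c("cingulum", "posterior_ventral",
                            "anterior_ventral", "arcuate", "projection")
wm_assoc_clusters <- function() wm_clusters()[1:4]

#' Names of the measurement-model architectures
#'
#' The twelve competing confirmatory factor architectures over the 10
#' cluster-average indicators (5 bilateral functional systems x 2
#' hemispheres), spanning indicator-only, single-factor, bifactor
#' (association/projection or hemispheres), hierarchical, and bilateral
#' cluster-latent variants. `"BiClusHem-BiF"` and `"HiBiClusHem-BiF"` are
#' accepted aliases for the two hemisphere-bifactor bilateral models.
#'
#' @return character vector of the 12 canonical names.
#' @export
wm_model_names <- function() c(
  "clustered_indicator_only",
  "clustered_single_factor",
  "clustered_bifactor",
  "clustered_hemisphere_bifactor",
  "clustered_hierarchical",
  "clustered_hierarchical_hemisphere_bifactor",
  "bilateral_clustered_indicator_only",
  "bilateral_clustered_single_factor",
  "bilateral_clustered_bifactor",
  "bilateral_clustered_hemisphere_bifactor",
  "bilateral_clustered_hierarchical",
  "bilateral_clustered_hierarchical_hemisphere_bifactor")

resolve_model_name <- function(name) {
  alias <- c("BiClusHem-BiF" = "bilateral_clustered_hemisphere_bifactor",
             "HiBiClusHem-BiF" = "bilateral_clustered_hierarchical_hemisphere_bifactor")
  if (name %in% names(alias)) name <- alias[[name]]
  if (!name %in% wm_model_names()) stop("unknown model name: ", name)
  name
}

#' @rdname wm_clusters
#' @export
wm_indicators <- function(prefix = "") {
  as.vector(t(outer(paste0(prefix, wm_clusters()), c("L", "R"), paste, sep = "_")))
}

# Equality rule: any latent measured by exactly two (free, unlabelled)
# loadings gets a shared label — the local-identifiability convention for
# two-indicator latents.
apply_two_indicator_rule <- function(rows) {
  lo <- rows$op == "=~"
  for (lat in unique(rows$lhs[lo])) {
    ix <- which(lo & rows$lhs == lat)
    if (length(ix) == 2L && all(rows$free[ix]) &&
        all(rows$label[ix] == "")) {
      rows$label[ix] <- paste0("eq_", lat)
    }
  }
  rows
}

measurement_rows <- function(name, prefix = "") {
  name <- resolve_model_name(name)
  cl <- wm_clusters(); acl <- wm_assoc_clusters()
  ind <- function(c, h) paste0(prefix, c, "_", h)
  observed <- wm_indicators(prefix)
  g <- paste0("g", if (nzchar(prefix)) sub("_$", "", prefix) else "WM")
  bl <- function(c) paste0(prefix, "bl_", c)
  hemL <- paste0(prefix, "hem_L"); hemR <- paste0(prefix, "hem_R")
  assoc <- paste0(prefix, "assoc"); proj <- paste0(prefix, "proj")
  assoc_inds <- as.vector(sapply(acl, function(c) c(ind(c, "L"), ind(c, "R"))))
  proj_inds <- c(ind("projection", "L"), ind("projection", "R"))
  left_inds <- paste0(prefix, cl, "_L"); right_inds <- paste0(prefix, cl, "_R")

  loads <- function(lat, targets) do.call(rbind, lapply(targets, function(t)
    pt_row(lat, "=~", t)))
  latvar <- function(lats) do.call(rbind, lapply(lats, function(l)
    pt_row(l, "~~", l, free = FALSE, value = 1)))
  orth <- function(a, b) pt_row(a, "~~", b, free = FALSE, value = 0)

  latents <- character(); rows <- NULL
  cov_targets <- character()   # latents that carry covariate regressions
  add <- function(...) rbind(rows, ...)

  if (name == "clustered_indicator_only") {
    # independent manifest variables, no latent structure
  } else if (name == "clustered_single_factor") {
    latents <- g
    cov_targets <- g
    rows <- add(loads(g, observed), latvar(g))
  } else if (name == "clustered_bifactor") {
    latents <- c(g, assoc, proj)
    cov_targets <- g
    rows <- add(loads(g, observed), loads(assoc, assoc_inds),
                loads(proj, proj_inds), latvar(latents),
                orth(g, assoc), orth(g, proj), orth(assoc, proj))
  } else if (name == "clustered_hemisphere_bifactor") {
    latents <- c(g, hemL, hemR)
    cov_targets <- g
    rows <- add(loads(g, observed), loads(hemL, left_inds),
                loads(hemR, right_inds), latvar(latents),
                orth(g, hemL), orth(g, hemR), orth(hemL, hemR))
  } else if (name == "clustered_hierarchical") {
    latents <- c(g, assoc, proj)
    cov_targets <- c(assoc, proj)
    rows <- add(loads(g, c(assoc, proj)), loads(assoc, assoc_inds),
                loads(proj, proj_inds), latvar(latents))
  } else if (name == "clustered_hierarchical_hemisphere_bifactor") {
    latents <- c(g, assoc, proj, hemL, hemR)
    cov_targets <- c(assoc, proj)
    rows <- add(loads(g, c(assoc, proj)), loads(assoc, assoc_inds),
                loads(proj, proj_inds), loads(hemL, left_inds),
                loads(hemR, right_inds), latvar(latents),
                orth(g, hemL), orth(g, hemR), orth(hemL, hemR))
  } else if (name == "bilateral_clustered_indicator_only") {
    latents <- bl(cl)
    cov_targets <- bl(cl)
    rows <- add(do.call(rbind, lapply(cl, function(c)
      loads(bl(c), c(ind(c, "L"), ind(c, "R"))))), latvar(latents))
    pairs <- utils::combn(latents, 2L)
    rows <- add(do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
      pt_row(pairs[1, i], "~~", pairs[2, i], free = TRUE, value = 0.3))))
  } else if (name == "bilateral_clustered_single_factor") {
    latents <- c(g, bl(cl))
    cov_targets <- bl(cl)
    rows <- add(loads(g, bl(cl)), do.call(rbind, lapply(cl, function(c)
      loads(bl(c), c(ind(c, "L"), ind(c, "R"))))), latvar(latents))
  } else if (name == "bilateral_clustered_bifactor") {
    latents <- c(g, bl(cl), assoc)
    cov_targets <- bl(cl)
    rows <- add(loads(g, bl(cl)), do.call(rbind, lapply(cl, function(c)
      loads(bl(c), c(ind(c, "L"), ind(c, "R"))))),
      loads(assoc, bl(acl)), latvar(latents), orth(g, assoc))
  } else if (name == "bilateral_clustered_hemisphere_bifactor") {
    latents <- c(g, bl(cl), hemL, hemR)
    cov_targets <- bl(cl)
    rows <- add(loads(g, bl(cl)), do.call(rbind, lapply(cl, function(c)
      loads(bl(c), c(ind(c, "L"), ind(c, "R"))))),
      loads(hemL, left_inds), loads(hemR, right_inds), latvar(latents),
      orth(g, hemL), orth(g, hemR), orth(hemL, hemR))
  } else if (name == "bilateral_clustered_hierarchical") {
    latents <- c(g, assoc, bl(cl))
    cov_targets <- bl(cl)
    rows <- add(loads(g, c(assoc, bl("projection"))),
                loads(assoc, bl(acl)),
                do.call(rbind, lapply(cl, function(c)
                  loads(bl(c), c(ind(c, "L"), ind(c, "R"))))),
                latvar(latents))
  } else if (name == "bilateral_clustered_hierarchical_hemisphere_bifactor") {
    latents <- c(g, assoc, bl(cl), hemL, hemR)
    cov_targets <- bl(cl)
    rows <- add(loads(g, c(assoc, bl("projection"))),
                loads(assoc, bl(acl)),
                do.call(rbind, lapply(cl, function(c)
                  loads(bl(c), c(ind(c, "L"), ind(c, "R"))))),
                loads(hemL, left_inds), loads(hemR, right_inds),
                latvar(latents),
                orth(g, hemL), orth(g, hemR), orth(hemL, hemR))
  }

  resid <- do.call(rbind, lapply(observed, function(v) pt_row(v, "~~", v)))
  ints <- do.call(rbind, lapply(observed, function(v)
    pt_row(v, "~1", v, free = TRUE, value = 0)))
  rows <- rbind(rows, resid, ints)
  rows <- apply_two_indicator_rule(rows)
  list(observed = observed, latents = latents, rows = rows,
       cov_targets = cov_targets,
       g = if (name %in% c("clustered_indicator_only",
                           "bilateral_clustered_indicator_only")) NULL else g)
}

#' Build one of the twelve measurement models
#'
#' Constructs a [wm_model_spec()] for an architecture from
#' [wm_model_names()]. All latent variables have their (residual) variance
#' fixed to 1 with freely estimated loadings; latents measured by exactly two
#' variables get equality-constrained loadings; bifactor group factors are
#' orthogonal to the general factor and to each other (explicit `fixed(0)`
#' covariances).
#'
#' @param name architecture name or alias (see [wm_model_names()]).
#' @param marker optional marker tag (`"FA"`, `"INVF"`, `"MTR"`); when given,
#'   all variable names are prefixed `"<marker>_"` and the general factor is
#'   named `g<marker>`.
#' @param source_dummy include a data-source dummy regressor pointing to all
#'   exogenous latents and the residuals of all endogenous latents (to the
#'   indicators themselves in the indicator-only model)?
#' @param age include a regression of every latent variable on
#'   (residualized) age?
#' @param source_var,age_var observed column names for the covariates.
#' @return a [wm_model_spec()].
#' @export
build_measurement_model <- function(name, marker = NULL, source_dummy = FALSE,
                                    age = FALSE, source_var = "source",
                                    age_var = "age_resid") {
  prefix <- if (is.null(marker)) "" else paste0(marker, "_")
  parts <- measurement_rows(name, prefix)
  spec_parts <- add_covariates(parts, source_dummy, age, source_var, age_var)
  wm_model_spec(spec_parts$observed, spec_parts$latents, spec_parts$rows)
}

# Covariates enter as observed exogenous variables with free mean/variance.
# They regress on the cluster-level common factors carrying the indicators'
# shared variance (`parts$cov_targets`; the indicators themselves when the
# model has no latents). Upstream general factors are skipped — their
# covariate slope is perfectly collinear with the downstream latents' slopes
# (rank-deficient information) — and so are the orthogonal bifactor group
# factors, whose unit-residual scaling makes a covariate slope trade off
# almost flatly against vanishing loadings. `source_targets` further
# restricts the dummy's regressions (a latent whose indicators exist at one
# site only carries no information about a site contrast).
add_covariates <- function(parts, source_dummy, age, source_var, age_var,
                           source_targets = NULL) {
  covs <- c(if (source_dummy) source_var, if (age) age_var)
  if (!length(covs)) return(parts)
  targets <- if (length(parts$cov_targets)) parts$cov_targets
             else if (!length(parts$latents)) parts$observed
             else parts$latents
  tgt <- function(cv) {
    if (cv == source_var && !is.null(source_targets))
      intersect(targets, source_targets)
    else targets
  }
  reg <- do.call(rbind, unlist(lapply(covs, function(cv)
    lapply(tgt(cv), function(t) pt_row(t, "~", cv, free = TRUE, value = 0))),
    recursive = FALSE))
  cov_rows <- do.call(rbind, lapply(covs, function(cv)
    rbind(pt_row(cv, "~~", cv, free = TRUE, value = 0.5),
          pt_row(cv, "~1", cv, free = TRUE, value = 0))))
  if (length(covs) == 2L)
    cov_rows <- rbind(cov_rows, pt_row(covs[1], "~~", covs[2], free = TRUE,
                                       value = 0))
  parts$observed <- c(parts$observed, covs)
  parts$rows <- rbind(parts$rows, reg, cov_rows)
  parts
}

#' Measurement model for fluid intelligence
#'
#' One latent (`gFluid`) measured by the proportions of correctly solved
#' odd- and even-numbered matrix-reasoning items, with equality-constrained
#' loadings for local identifiability and latent variance fixed to 1.
#'
#' @inheritParams build_measurement_model
#' @export
build_intelligence_model <- function(source_dummy = FALSE, age = FALSE,
                                     source_var = "source",
                                     age_var = "age_resid") {
  parts <- intelligence_rows()
  parts <- add_covariates(parts, source_dummy, age, source_var, age_var)
  wm_model_spec(parts$observed, parts$latents, parts$rows)
}

intelligence_rows <- function() {
  observed <- c("gf_odd", "gf_even")
  rows <- rbind(
    pt_row("gFluid", "=~", "gf_odd"), pt_row("gFluid", "=~", "gf_even"),
    pt_row("gFluid", "~~", "gFluid", free = FALSE, value = 1),
    pt_row("gf_odd", "~~", "gf_odd"), pt_row("gf_even", "~~", "gf_even"),
    pt_row("gf_odd", "~1", "gf_odd", free = TRUE, value = 0),
    pt_row("gf_even", "~1", "gf_even", free = TRUE, value = 0))
  rows <- apply_two_indicator_rule(rows)
  list(observed = observed, latents = "gFluid", rows = rows)
}

#' Build a joint multi-marker model
#'
#' Combines per-marker measurement architectures into one model. In
#' `"correlated"` mode the marker general factors covary freely while all
#' other cross-marker covariances stay fixed at zero; in `"hierarchical"`
#' mode a second-order factor `gWM` is extracted from the three general
#' factors. Optional additions: five orthogonal method factors (one per
#' functional cluster, loading that cluster's bilateral latent in every
#' marker), a latent fluid-intelligence outcome regressed on the general
#' factors, and source/age covariates.
#'
#' @param architecture a single architecture name, or a named character
#'   vector per marker (e.g. a hierarchical variant for MTR only). Only
#'   architectures with bilateral cluster latents and a general factor are
#'   meaningful here.
#' @param markers marker tags, subset of `c("FA", "INVF", "MTR")`.
#' @param mode `"correlated"` or `"hierarchical"`.
#' @param method_factors add the five orthogonal per-cluster method factors?
#' @param intelligence add the fluid-intelligence measurement model and the
#'   structural regressions `gFluid ~ g<marker>`?
#' @param source_dummy,age,source_var,age_var as in
#'   [build_measurement_model()].
#' @param single_site_markers markers acquired at one site only (default
#'   `"MTR"` when the dummy is on): their latents carry no information about
#'   the site contrast, so the source dummy does not regress on them.
#' @return a [wm_model_spec()].
#' @export
build_joint_model <- function(architecture = "bilateral_clustered_hemisphere_bifactor",
                              markers = c("FA", "INVF", "MTR"),
                              mode = c("correlated", "hierarchical"),
                              method_factors = FALSE, intelligence = FALSE,
                              source_dummy = FALSE, age = FALSE,
                              source_var = "source", age_var = "age_resid",
                              single_site_markers = intersect("MTR", markers)) {
  mode <- match.arg(mode)
  stopifnot(length(markers) >= 2L)
  if (length(architecture) == 1L && is.null(names(architecture)))
    architecture <- stats::setNames(rep(architecture, length(markers)), markers)
  arch <- architecture[markers]
  parts_list <- lapply(markers, function(m)
    measurement_rows(resolve_model_name(arch[[m]]), paste0(m, "_")))
  names(parts_list) <- markers
  if (any(vapply(parts_list, function(p) is.null(p$g), logical(1))))
    stop("joint models require architectures with a general factor")
  gs <- vapply(parts_list, function(p) p$g, character(1))

  observed <- unlist(lapply(parts_list, `[[`, "observed"), use.names = FALSE)
  latents <- unlist(lapply(parts_list, `[[`, "latents"), use.names = FALSE)
  rows <- do.call(rbind, lapply(parts_list, `[[`, "rows"))

  if (mode == "correlated") {
    pairs <- utils::combn(gs, 2L)
    rows <- rbind(rows, do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
      pt_row(pairs[1, i], "~~", pairs[2, i], free = TRUE, value = 0.2))))
  } else {
    gwm <- "gWM"
    latents <- c(latents, gwm)
    rows <- rbind(rows,
                  do.call(rbind, lapply(gs, function(g) pt_row(gwm, "=~", g))),
                  pt_row(gwm, "~~", gwm, free = FALSE, value = 1))
  }

  if (method_factors) {
    for (clu in wm_clusters()) {
      mf <- paste0("meth_", clu)
      latents <- c(latents, mf)
      targets <- paste0(markers, "_bl_", clu)
      rows <- rbind(rows,
                    do.call(rbind, lapply(targets, function(t)
                      pt_row(mf, "=~", t))),
                    pt_row(mf, "~~", mf, free = FALSE, value = 1),
                    do.call(rbind, lapply(gs, function(g)
                      pt_row(mf, "~~", g, free = FALSE, value = 0))))
    }
  }

  if (intelligence) {
    ip <- intelligence_rows()
    observed <- c(observed, ip$observed)
    latents <- c(latents, ip$latents)
    rows <- rbind(rows, ip$rows,
                  do.call(rbind, lapply(gs, function(g)
                    pt_row("gFluid", "~", g, free = TRUE, value = 0))))
  }

  rows <- apply_two_indicator_rule(rows)
  cov_targets <- unlist(lapply(parts_list, `[[`, "cov_targets"),
                        use.names = FALSE)
  if (intelligence) cov_targets <- c(cov_targets, "gFluid")
  parts <- list(observed = observed, latents = latents, rows = rows,
                cov_targets = cov_targets)
  src_targets <- NULL
  if (source_dummy && length(single_site_markers)) {
    excluded <- unlist(lapply(single_site_markers, function(m)
      parts_list[[m]]$latents))
    src_targets <- setdiff(latents, excluded)
  }
  parts <- add_covariates(parts, source_dummy, age, source_var, age_var,
                          source_targets = src_targets)
  wm_model_spec(parts$observed, parts$latents, parts$rows)
}

#' Residualize age on data-set source
#'
#' Ordinary least-squares residuals of age on an intercept and the source
#' indicator, so that the age covariate is orthogonal to the site contrast;
#' the residuals have mean zero within each site.
#'
#' @param age numeric vector of ages in years.
#' @param site site factor/vector (two levels expected).
#' @return numeric vector of residualized ages.
#' @export
residualize_age <- function(age, site) {
  stopifnot(length(age) == length(site))
  if (length(unique(site)) < 2L) {
    warning("only one site present; returning centered age")
    return(age - mean(age))
  }
  unname(stats::residuals(stats::lm(age ~ factor(site))))
}
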