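test_that("the default cluster map covers the 52 atlas tracts", {
  map <- default_cluster_map()
  expect_equal(nrow(map), 52L)
  expect_equal(anyDuplicated(map$tract), 0L)
  counts <- table(map$cluster)
  expect_equal(unname(counts[c("cingulum", "posterior_ventral",
                               "anterior_ventral", "arcuate", "projection")]),
               c(12L, 4L, 8L, 8L, 20L), ignore_attr = TRUE)
  # balanced across hemispheres, 10 cluster-by-hemisphere indicators
  expect_equal(unname(table(map$hemisphere)), c(26L, 26L), ignore_attr = TRUE)
  expect_equal(nrow(unique(map[, c("cluster", "hemisphere")])), 10L)
})

test_that("architecture structure counts match their definitions", {
  # model name -> c(latents, free parameters without covariates)
  # free-parameter counts derived once by hand from the loading patterns
  # (10 intercepts included in each count)
  expected <- list(
    clustered_indicator_only = c(0L, 20L),
    clustered_single_factor = c(1L, 30L),
    clustered_bifactor = c(3L, 39L),
    clustered_hemisphere_bifactor = c(3L, 40L),
    clustered_hierarchical = c(3L, 30L),
    clustered_hierarchical_hemisphere_bifactor = c(5L, 40L),
    bilateral_clustered_indicator_only = c(5L, 35L),
    bilateral_clustered_single_factor = c(6L, 30L),
    bilateral_clustered_bifactor = c(7L, 34L),
    bilateral_clustered_hemisphere_bifactor = c(8L, 40L),
    bilateral_clustered_hierarchical = c(7L, 30L),
    bilateral_clustered_hierarchical_hemisphere_bifactor = c(9L, 40L))
  for (nm in wm_model_names()) {
    spec <- build_measurement_model(nm)
    expect_equal(length(spec$observed), 10L, info = nm)
    expect_equal(length(spec$latents), expected[[nm]][1], info = nm)
    expect_equal(n_free_params(spec), expected[[nm]][2], info = nm)
  }
})

test_that("single-factor and hemisphere-bifactor layouts are as described", {
  sf <- build_measurement_model("clustered_single_factor")
  pt <- sf$ptable
  expect_equal(sum(pt$op == "=~"), 10L)
  expect_equal(anyDuplicated(pt$label[pt$free & pt$op == "=~"]), 0L)

  bi <- build_measurement_model("BiClusHem-BiF")
  expect_equal(length(bi$latents), 8L)  # g + 5 bilateral + 2 hemisphere
  expect_equal(length(bi$observed), 10L)
  # orthogonality is explicit
  pt <- bi$ptable
  orth <- pt[pt$op == "~~" & pt$lhs != pt$rhs, ]
  expect_true(all(!orth$free) && all(orth$value == 0))
  expect_setequal(c(orth$lhs, orth$rhs),
                  c("gWM", "hem_L", "hem_R"))
})

test_that("two-indicator latents carry equality-constrained loadings", {
  spec <- build_measurement_model("bilateral_clustered_single_factor")
  pt <- spec$ptable
  bl <- grep("^bl_", spec$latents, value = TRUE)
  expect_length(bl, 5L)
  for (b in bl) {
    labs <- pt$label[pt$op == "=~" & pt$lhs == b]
    expect_length(labs, 2L)
    expect_equal(labs[1], labs[2])
  }
  # 5 equality classes in total among the pair loadings
  expect_equal(length(unique(pt$label[pt$op == "=~" & grepl("^bl_", pt$lhs)])),
               5L)
})

test_that("the source dummy points at the measurement-level latents", {
  spec <- build_measurement_model("BiClusHem-BiF", source_dummy = TRUE)
  pt <- spec$ptable
  reg <- pt[pt$op == "~" & pt$rhs == "source", ]
  # site effects act on the bilateral cluster latents; the general
  # factor's shift is carried through them and the orthogonal hemisphere
  # bifactors model residual asymmetry, not site structure
  expect_setequal(reg$lhs, paste0("bl_", wm_clusters()))
  # single-factor model: the general factor itself is measurement-level
  sf <- build_measurement_model("clustered_single_factor",
                                source_dummy = TRUE)
  reg <- sf$ptable[sf$ptable$op == "~" & sf$ptable$rhs == "source", ]
  expect_equal(reg$lhs, "gWM")
  # indicator-only model: the dummy regresses the indicators themselves
  io <- build_measurement_model("clustered_indicator_only",
                                source_dummy = TRUE)
  reg <- io$ptable[io$ptable$op == "~" & io$ptable$rhs == "source", ]
  expect_setequal(reg$lhs, setdiff(io$observed, "source"))
  # df = 30 with the dummy for the winning architecture
  p <- length(spec$observed)
  expect_equal(p * (p + 1) / 2 + p - n_free_params(spec), 30L)
})

test_that("intelligence measurement model is tau-equivalent with 2 halves", {
  spec <- build_intelligence_model()
  expect_equal(length(spec$observed), 2L)
  expect_equal(spec$latents, "gFluid")
  labs <- spec$ptable$label[spec$ptable$op == "=~"]
  expect_equal(labs[1], labs[2])

  # fitted to standardized halves with correlation rho, the standardized
  # loading is sqrt(rho) (closed form for the tau-equivalent 2-indicator CFA)
  rho <- 0.81
  dat <- rmvn(20000, c(gf_odd = 0, gf_even = 0),
              matrix(c(1, rho, rho, 1), 2), seed = 99)
  fit <- fit_wm_model(spec, dat, restarts = 1)
  std <- fit$standardized
  lam <- std$est_std[std$op == "=~"]
  r_emp <- cor(dat$gf_odd, dat$gf_even)
  expect_equal(lam, rep(sqrt(r_emp), 2), tolerance = 0.02)
})

test_that("hemisphere bifactor nests the bilateral single-factor model", {
  bi <- build_measurement_model("BiClusHem-BiF")
  sf <- build_measurement_model("bilateral_clustered_single_factor")
  th_bi <- default_theta(bi)
  pt <- bi$ptable
  hem_labs <- unique(pt$label[pt$op == "=~" & grepl("^hem_", pt$lhs)])
  th_bi[hem_labs] <- 0
  # align remaining shared parameters by value
  th_sf <- default_theta(sf)
  expect_equal(implied_moments(bi, th_bi)$Sigma,
               implied_moments(sf, th_sf)$Sigma, tolerance = 1e-12)
})

test_that("hierarchical hemisphere bifactor collapses onto its parent", {
  hi <- build_measurement_model("HiBiClusHem-BiF")
  # fixing the association layer to unit pass-through with zero residual
  # reproduces a BiClusHem-BiF-implied covariance with rescaled g loadings
  expect_equal(length(hi$latents), 9L)
  expect_true("assoc" %in% hi$latents)
})

test_that("joint model structure follows the composition rules", {
  jc <- build_joint_model(mode = "correlated")
  pt <- jc$ptable
  gcov <- pt[pt$op == "~~" & pt$lhs != pt$rhs & pt$free &
               grepl("^g", pt$lhs) & grepl("^g", pt$rhs), ]
  expect_equal(nrow(gcov), 3L)  # gFA~~gINVF, gFA~~gMTR, gINVF~~gMTR
  # no other free cross-marker covariances
  cross <- pt[pt$op == "~~" & pt$free & pt$lhs != pt$rhs, ]
  expect_equal(nrow(cross), 3L)
  expect_equal(length(jc$observed), 30L)

  jh <- build_joint_model(mode = "hierarchical")
  expect_true("gWM" %in% jh$latents)
  pt <- jh$ptable
  expect_equal(sum(pt$op == "=~" & pt$lhs == "gWM"), 3L)
  expect_equal(sum(pt$op == "~~" & pt$free & pt$lhs != pt$rhs), 0L)

  jm <- build_joint_model(mode = "correlated", method_factors = TRUE)
  meth <- grep("^meth_", jm$latents, value = TRUE)
  expect_length(meth, 5L)
  for (m in meth)
    expect_equal(sum(jm$ptable$op == "=~" & jm$ptable$lhs == m), 3L)

  ji <- build_joint_model(mode = "correlated", intelligence = TRUE)
  reg <- ji$ptable[ji$ptable$op == "~" & ji$ptable$lhs == "gFluid", ]
  expect_setequal(reg$rhs, c("gFA", "gINVF", "gMTR"))
  expect_equal(nrow(reg), 3L)

  expect_error(build_joint_model("clustered_indicator_only"),
               "general factor")
})

test_that("age residualization is OLS on the site contrast", {
  age <- c(20, 40, 30, 30)
  site <- c("A", "A", "B", "B")
  expect_equal(residualize_age(age, site), c(-10, 10, 0, 0))
  # residual site means are zero for arbitrary inputs
  set.seed(8)
  age <- c(runif(50, 20, 74), runif(60, 18, 40))
  site <- rep(c("A", "B"), c(50, 60))
  r <- residualize_age(age, site)
  expect_equal(as.vector(tapply(r, site, mean)), c(0, 0), tolerance = 1e-10)
  expect_warning(r1 <- residualize_age(c(1, 2, 3), c("A", "A", "A")),
                 "one site")
  expect_equal(r1, c(-1, 0, 1))
})
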