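test_that("ML discrepancy matches hand arithmetic and is zero at S", {
  S <- matrix(c(2, 0.6, 0.6, 1.5), 2)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # p = 1 cases
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2),
               tolerance = 1e-12)
  expect_equal(ml_discrepancy(matrix(1), matrix(2)), log(2) - 0.5,
               tolerance = 1e-12)
  expect_gt(ml_discrepancy(S, S * 1.3), 0)
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), S), "positive definite")
})

test_that("casewise log-likelihood matches direct normal densities", {
  # 1 variable, 1 case, standard normal at 0: -log(2*pi)/2
  spec <- saturated_spec("y")
  th <- c(1, 0); names(th) <- free_param_labels(spec)
  expect_equal(casewise_loglik(spec, th, data.frame(y = 0)),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # complete data: equals the direct p-variate normal log-likelihood
  spec3 <- saturated_spec(c("a", "b", "c"))
  th <- default_theta(spec3)
  th[] <- c(1.2, 0.8, 1.5, 0.3, -0.2, 0.1, 0.5, 0, -0.5)
  mom <- implied_moments(spec3, th)
  Y <- rmvn(40, mom$mu, mom$Sigma, seed = 5)
  ll <- casewise_loglik(spec3, th, Y)
  expect_equal(ll, direct_mvn_loglik(Y, mom$mu, mom$Sigma), tolerance = 1e-8)

  # additivity: duplicating every row doubles the log-likelihood
  expect_equal(casewise_loglik(spec3, th, rbind(Y, Y)), 2 * ll,
               tolerance = 1e-8)
})

test_that("FIML on complete data equals complete-data ML", {
  spec <- single_factor_spec(4)
  dat <- simulate_from_spec(spec, default_theta(spec), n = 300, seed = 21)
  sat <- fiml_saturated(as.matrix(dat))
  mu <- colMeans(dat)
  S <- crossprod(sweep(as.matrix(dat), 2, mu)) / nrow(dat)
  expect_equal(sat$mu, mu, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sat$Sigma, S, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sat$loglik, direct_mvn_loglik(dat, mu, S), tolerance = 1e-8)
})

test_that("saturated EM agrees with direct FIML optimization under missingness", {
  # dual route: EM for the unstructured model vs quasi-Newton maximization
  # of the same casewise likelihood through the generic engine
  spec <- saturated_spec(c("a", "b", "c"))
  th <- default_theta(spec)
  th[] <- c(1, 1.4, 0.9, 0.4, -0.1, 0.3, 0, 0.5, -0.5)
  mom <- implied_moments(spec, th)
  Y <- as.matrix(rmvn(150, mom$mu, mom$Sigma, seed = 77))
  set.seed(78)
  Y[sample(length(Y), 90)] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, ]
  em <- fiml_saturated(Y)
  fit <- fit_wm_model(spec, as.data.frame(Y), restarts = 1)
  expect_equal(em$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(em$Sigma, fit$Sigma_hat, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("the saturated spec reproduces the sample ML covariance", {
  spec <- saturated_spec(c("a", "b", "c"))
  set.seed(12)
  Y <- matrix(rnorm(240), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_wm_model(spec, as.data.frame(Y), restarts = 0)
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / nrow(Y)
  expect_equal(fit$Sigma_hat, S, tolerance = 1e-5, ignore_attr = TRUE)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$df, 0L)
})

test_that("single-factor loadings are recovered from simulated data", {
  spec <- single_factor_spec(5)
  th <- default_theta(spec)
  pt <- spec$ptable
  th[pt$label[pt$op == "=~"]] <- 0.7
  th[pt$label[pt$free & pt$op == "~~"]] <- 1 - 0.49
  dat <- simulate_from_spec(spec, th, n = 5000, seed = 13)
  set.seed(14)
  fit <- fit_wm_model(spec, dat, restarts = 1)
  lam <- fit$theta[unique(pt$label[pt$op == "=~"])]
  expect_true(all(lam > 0.65 & lam < 0.75))
  expect_true(fit$converged)
  expect_true(check_validity(fit)$admissible)
})

test_that("chi-square is nonnegative and invariant to variable order", {
  spec <- single_factor_spec(4)
  dat <- simulate_from_spec(spec, default_theta(spec), n = 400, seed = 31)
  set.seed(1); fit <- fit_wm_model(spec, dat, restarts = 1)
  expect_gte(fit$chi2, 0)
  expect_equal(fit$chi2, 2 * (fit$loglik_sat - fit$loglik), tolerance = 1e-8)
  # permuted observed order, same data
  perm <- c(3, 1, 4, 2)
  spec_p <- single_factor_spec(4, observed = paste0("y", perm))
  set.seed(1); fit_p <- fit_wm_model(spec_p, dat, restarts = 1)
  expect_equal(fit_p$chi2, fit$chi2, tolerance = 1e-4)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
})

heywood_fixture <- function(r12, r13, r23, n, seed) {
  Sigma <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  obs <- c("y1", "y2", "y3")
  spec <- wm_model_spec(obs, "f", rbind(
    do.call(rbind, lapply(obs, function(v) pt_row("f", "=~", v))),
    pt_row("f", "~~", "f", free = FALSE, value = 1),
    do.call(rbind, lapply(obs, function(v) pt_row(v, "~~", v))),
    do.call(rbind, lapply(obs, function(v) pt_row(v, "~1", v, TRUE, 0)))))
  dat <- rmvn(n, c(y1 = 0, y2 = 0, y3 = 0), Sigma, seed = seed)
  set.seed(seed + 1)
  fit_wm_model(spec, dat, variance_scale = "raw", restarts = 1)
}

test_that("non-significant negative variances are fixed to zero on refit", {
  # population residual variance of y1 is slightly negative
  # (lambda1^2 = .75*.75/.55 > 1), sampling puts the estimate just below 0
  fit <- heywood_fixture(.75, .75, .55, n = 500, seed = 31)
  expect_equal(nrow(fit$heywood), 1L)
  expect_gte(fit$heywood$p_value[1], 0.05)
  set.seed(3)
  res <- apply_negative_variance_rule(fit, restarts = 1)
  expect_equal(res$fixed, fit$heywood$label)
  expect_equal(res$fit$df, fit$df + 1L)
  expect_equal(nrow(res$fit$heywood), 0L)
})

test_that("significant negative variances are left free and flagged", {
  fit <- heywood_fixture(.9, .9, .65, n = 2000, seed = 32)
  expect_equal(nrow(fit$heywood), 1L)
  expect_lt(fit$heywood$p_value[1], 0.05)
  set.seed(3)
  res <- apply_negative_variance_rule(fit, restarts = 1)
  expect_length(res$fixed, 0L)
  expect_equal(res$flagged, "y1")
})

test_that("models with no negative variances pass through unchanged", {
  spec <- single_factor_spec(3)
  dat <- simulate_from_spec(spec, default_theta(spec), n = 300, seed = 41)
  set.seed(42)
  fit <- fit_wm_model(spec, dat, variance_scale = "raw", restarts = 1)
  expect_equal(nrow(fit$heywood), 0L)
  res <- apply_negative_variance_rule(fit, restarts = 1)
  expect_identical(res$fit$spec$ptable, spec$ptable)
  expect_length(res$fixed, 0L)
})

test_that("admissibility verdicts react to non-positive-definite matrices", {
  spec <- single_factor_spec(3)
  dat <- simulate_from_spec(spec, default_theta(spec), n = 300, seed = 51)
  set.seed(52)
  fit <- fit_wm_model(spec, dat, restarts = 1)
  expect_true(check_validity(fit)$admissible)
  # eigenvalue below -tol in the latent covariance block
  bad <- fit
  bad$Sigma_all["f", "f"] <- -0.01
  v <- check_validity(bad)
  expect_false(v$admissible)
  expect_match(paste(v$reasons, collapse = " "), "latent covariance")
  # non-convergence is inadmissible
  bad2 <- fit; bad2$converged <- FALSE
  expect_false(check_validity(bad2)$admissible)
  # non-PD parameter vcov is inadmissible
  bad3 <- fit; bad3$npd_param_vcov <- TRUE
  expect_false(check_validity(bad3)$admissible)
})

test_that("standard errors match the inverse observed information", {
  # saturated univariate model: Var(mean) = sigma^2/n, Var(sigma2) = 2 sigma^4/n
  spec <- saturated_spec("y")
  set.seed(61)
  dat <- data.frame(y = rnorm(4000, 1, 2))
  fit <- fit_wm_model(spec, dat, restarts = 0)
  s2 <- mean((dat$y - mean(dat$y))^2)
  lab_var <- free_param_labels(spec)[1]
  lab_mu <- free_param_labels(spec)[2]
  expect_equal(unname(fit$se[lab_mu]), sqrt(s2 / 4000), tolerance = 0.02)
  expect_equal(unname(fit$se[lab_var]), sqrt(2 * s2^2 / 4000),
               tolerance = 0.02)
})
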