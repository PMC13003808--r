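#' Maximum likelihood discrepancy between two covariance matrices
#'
#' The classic normal-theory ML fit function
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, which is nonnegative and
#' zero iff `Sigma == S`.
#'
#' @param S sample covariance matrix (symmetric positive definite).
#' @param Sigma model-implied covariance matrix of the same dimension.
#' @return scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  stopifnot(is.matrix(S), is.matrix(Sigma), all(dim(S) == dim(Sigma)))
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive definite"))
  cSig <- tryCatch(chol(Sigma),
                   error = function(e) stop("Sigma is not positive definite"))
  ld_S <- 2 * sum(log(diag(cS)))
  ld_Sig <- 2 * sum(log(diag(cSig)))
  ld_Sig + sum(diag(chol2inv(cSig) %*% S)) - ld_S - p
}

# ---- missingness-pattern sufficient statistics -------------------------------

# Group rows of Y by missingness pattern; per pattern keep count, mean and
# ML scatter (divisor n_k). Likelihood evaluations then cost O(#patterns p^3),
# independent of n.
pattern_stats <- function(Y) {
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L))
    stop("rows with no observed values are not allowed")
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(ix) {
    o <- which(obs[ix[1L], ])
    Yk <- Y[ix, o, drop = FALSE]
    mk <- colMeans(Yk)
    Ck <- crossprod(sweep(Yk, 2L, mk)) / length(ix)
    list(obs = o, n = length(ix), mean = mk, scatter = Ck)
  })
  unname(out)
}

# Observed-data log-likelihood of (mu, Sigma) given pattern stats.
# Returns -Inf if any pattern submatrix is not positive definite.
loglik_patterns <- function(patterns, mu, Sigma) {
  ll <- 0
  for (pk in patterns) {
    o <- pk$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Si <- chol2inv(ch)
    d <- pk$mean - mu[o]
    ll <- ll - pk$n / 2 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                             sum(Si * pk$scatter) + drop(d %*% Si %*% d))
  }
  ll
}

#' Casewise (full-information) log-likelihood
#'
#' Sums, over the rows of `data`, the multivariate normal log density of each
#' row's observed subset under the subset-marginalized model-implied moments.
#' On complete data this equals the ordinary joint normal log-likelihood;
#' missing cells are simply marginalized out, which is what makes planned
#' missingness (e.g. a marker acquired at one site only) estimable.
#'
#' @param spec a [wm_model_spec()].
#' @param theta free-parameter vector.
#' @param data data frame or matrix containing `spec$observed` columns;
#'   `NA` marks missing.
#' @return scalar log-likelihood.
#' @export
casewise_loglik <- function(spec, theta, data) {
  Y <- spec_data_matrix(spec, data)
  mom <- implied_moments(spec, theta)
  loglik_patterns(pattern_stats(Y), mom$mu, mom$Sigma)
}

spec_data_matrix <- function(spec, data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  miss <- setdiff(spec$observed, names(data))
  if (length(miss)) stop("data is missing model variable(s): ",
                         paste(miss, collapse = ", "))
  Y <- as.matrix(data[, spec$observed, drop = FALSE])
  storage.mode(Y) <- "double"
  Y
}

# ---- saturated and independence models ---------------------------------------

#' Saturated (unstructured) FIML estimate
#'
#' ML estimate of an unstructured mean vector and covariance matrix. With
#' complete data this is the closed-form ML solution (covariance divisor `n`);
#' with missing data it runs the standard EM algorithm for the multivariate
#' normal, iterating conditional-expectation sweeps per missingness pattern
#' until the observed-data log-likelihood is stationary.
#'
#' @param Y numeric matrix (rows = cases), `NA` for missing cells.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit iteration cap for EM.
#' @return list with `mu`, `Sigma`, `loglik`, `iterations`.
#' @export
fiml_saturated <- function(Y, tol = 1e-10, maxit = 1000L) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  patterns <- pattern_stats(Y)
  if (!anyNA(Y)) {
    mu <- colMeans(Y)
    Sigma <- crossprod(sweep(Y, 2L, mu)) / n
    return(list(mu = mu, Sigma = Sigma,
                loglik = loglik_patterns(patterns, mu, Sigma),
                iterations = 0L))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  ll_old <- loglik_patterns(patterns, mu, Sigma)
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  row_groups <- split(seq_len(n), key)
  for (it in seq_len(maxit)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    # E-step, vectorized within missingness pattern
    for (ix in row_groups) {
      o <- which(obs[ix[1L], ]); m <- setdiff(seq_len(p), o)
      Yo <- Y[ix, o, drop = FALSE]
      if (length(m) == 0L) {
        sum_y[o] <- sum_y[o] + colSums(Yo)
        sum_yy[o, o] <- sum_yy[o, o] + crossprod(Yo)
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      W <- Sigma[m, o, drop = FALSE] %*% chol2inv(chol(Soo))
      Em <- matrix(mu[m], nrow = length(ix), ncol = length(m), byrow = TRUE) +
        sweep(Yo, 2L, mu[o]) %*% t(W)
      Cm <- Sigma[m, m, drop = FALSE] - W %*% Sigma[o, m, drop = FALSE]
      sum_y[o] <- sum_y[o] + colSums(Yo)
      sum_y[m] <- sum_y[m] + colSums(Em)
      sum_yy[o, o] <- sum_yy[o, o] + crossprod(Yo)
      sum_yy[o, m] <- sum_yy[o, m] + crossprod(Yo, Em)
      sum_yy[m, o] <- t(sum_yy[o, m, drop = FALSE])
      sum_yy[m, m] <- sum_yy[m, m] + crossprod(Em) + length(ix) * Cm
    }
    mu <- sum_y / n
    Sigma <- sum_yy / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_patterns(patterns, mu, Sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      return(list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it))
    }
    ll_old <- ll
  }
  warning("saturated-model EM reached the iteration cap")
  list(mu = mu, Sigma = Sigma, loglik = ll_old, iterations = maxit)
}

# Independence (baseline) model: free means and variances, zero covariances.
# With FIML this separates per column; closed-form ML on available cases.
fit_independence <- function(Y) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  ll <- 0
  for (j in seq_len(p)) {
    y <- Y[, j]; y <- y[!is.na(y)]
    mj <- mean(y); vj <- mean((y - mj)^2)
    if (vj <= 0) stop("baseline model: column ", j, " has zero variance")
    ll <- ll + sum(stats::dnorm(y, mj, sqrt(vj), log = TRUE))
  }
  q <- 2L * p
  list(loglik = ll, q = q, df = p * (p + 1L) / 2L + p - q)
}

# ---- analytic gradient -------------------------------------------------------

# Gradient of the observed-data log-likelihood with respect to (mu, Sigma)
# accumulated over missingness patterns:
#   d ll / d Sigma_OO = n_k/2 (W S_k W + W d d' W - W),  W = Sigma_OO^-1,
#   d ll / d mu_O     = n_k W d,                          d = ybar_k - mu_O.
# Returns the p x p matrix G and the p-vector gmu.
loglik_moment_gradient <- function(patterns, mu, Sigma) {
  p <- length(mu)
  G <- matrix(0, p, p)
  gmu <- numeric(p)
  for (pk in patterns) {
    o <- pk$obs
    ch <- tryCatch(chol(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    d <- pk$mean - mu[o]
    Wd <- drop(W %*% d)
    G[o, o] <- G[o, o] +
      pk$n / 2 * (W %*% pk$scatter %*% W + tcrossprod(Wd) - W)
    gmu[o] <- gmu[o] + pk$n * Wd
  }
  list(G = G, gmu = gmu)
}

# Chain rule from moment space to the free parameters through the RAM
# matrices: with B = (I - A)^-1, V = B S B', P the moment gradient embedded
# over all variables,
#   d ll / d A = 2 B' P V + (B' Fg) (B m)',
#   d ll / d S = B' P B (off-diagonal cells doubled),
#   d ll / d m = B' Fg.
loglik_theta_gradient <- function(spec, theta, patterns) {
  cm <- spec$compiled
  mats <- spec_matrices(spec, theta)
  k <- cm$k
  B <- tryCatch(solve(diag(k) - mats$A), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  V <- B %*% mats$S %*% t(B)
  nobs <- length(spec$observed)
  mu <- drop(B %*% mats$m)[seq_len(nobs)]
  mg <- loglik_moment_gradient(patterns, mu,
                               V[seq_len(nobs), seq_len(nobs), drop = FALSE])
  if (is.null(mg)) return(NULL)
  P <- matrix(0, k, k)
  P[seq_len(nobs), seq_len(nobs)] <- mg$G
  g_all <- c(rep(0, k)); g_all[seq_len(nobs)] <- mg$gmu
  BtP <- crossprod(B, P)
  grad_A <- 2 * BtP %*% V + tcrossprod(crossprod(B, g_all), B %*% mats$m)
  grad_S <- BtP %*% B
  grad_S <- grad_S + t(grad_S)      # doubles the off-diagonal cells ...
  diag(grad_S) <- diag(grad_S) / 2  # ... but not the variances
  grad_m <- drop(crossprod(B, g_all))
  # collect per parameter-table row, then sum into labels
  pt <- spec$ptable
  rowg <- numeric(nrow(pt))
  rowg[cm$A_rows] <- grad_A[cm$A_idx]
  rowg[cm$S_rows] <- grad_S[cm$S_idx]
  rowg[cm$M_rows] <- grad_m[cm$M_idx]
  out <- numeric(length(cm$labels))
  fr <- which(pt$free)
  for (i in fr) out[cm$theta_ix[i]] <- out[cm$theta_ix[i]] + rowg[i]
  out
}

# ---- full model estimation ---------------------------------------------------

#' Fit a model specification by (full-information) maximum likelihood
#'
#' Maximizes the casewise normal log-likelihood over the free parameters,
#' honoring equality classes. Variance parameters are optimized on the log
#' scale by default; `variance_scale = "raw"` leaves them unbounded so that
#' negative variance estimates (Heywood cases) are observable, which the
#' negative-variance handling rule requires. The saturated log-likelihood is
#' computed on the same missingness patterns ([fiml_saturated()]), giving
#' `chi2 = 2 (loglik_sat - loglik)` — a definition that remains valid under
#' missing data and reduces to the familiar statistic on complete data.
#'
#' Optimization uses a quasi-Newton method (`nlminb`, finite-difference
#' gradients) from conventional start values (loadings 0.5, variances 0.5,
#' regressions 0, intercepts at sample means), plus `restarts` runs from
#' jittered starts, keeping the best converged solution: bifactor likelihoods
#' can be multimodal. Jitter draws use the current RNG state, so seed before
#' fitting for exact reproducibility.
#'
#' @param spec a [wm_model_spec()].
#' @param data data frame with the observed variables; `NA` = missing.
#' @param variance_scale `"log"` (default) or `"raw"`.
#' @param restarts number of additional jittered starts (default 5).
#' @param jitter half-width of the uniform jitter on the working scale.
#' @param se compute standard errors from the observed information (numerical
#'   Hessian)? Disable for speed in large screening loops.
#' @param max_iterations optimizer iteration cap.
#' @return object of class `wm_fit`: estimates (`theta`, named), `loglik`,
#'   `loglik_sat`, `chi2`, `df`, `n_used`, `converged`, `se`, `vcov`,
#'   `heywood` (negative free variances with raw-scale Wald p-values),
#'   `npd_param_vcov` / `npd_latent_cov` flags, and the standardized solution.
#' @export
fit_wm_model <- function(spec, data, variance_scale = c("log", "raw"),
                         restarts = 5L, jitter = 0.3, se = TRUE,
                         max_iterations = 2000L) {
  variance_scale <- match.arg(variance_scale)
  Y <- spec_data_matrix(spec, data)
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  patterns <- pattern_stats(Y)
  labels <- free_param_labels(spec)
  q <- length(labels)
  df <- p * (p + 1L) / 2L + p - q
  if (df < 0L) stop("model has negative degrees of freedom (", df,
                    "): not identified")
  vlab <- variance_param_labels(spec)
  is_var <- labels %in% vlab

  start <- default_theta(spec)
  # data-driven starts: intercepts at column means, observed variances at
  # the sample variance (halved for indicators, which share variance with
  # their latents)
  pt <- spec$ptable
  int_free <- pt$op == "~1" & pt$free & pt$lhs %in% spec$observed
  if (any(int_free)) {
    cm <- colMeans(Y, na.rm = TRUE)
    start[pt$label[int_free]] <- cm[pt$lhs[int_free]]
  }
  cv <- apply(Y, 2L, stats::var, na.rm = TRUE)
  cv[!is.finite(cv) | cv <= 0] <- 1
  has_loading <- unique(pt$rhs[pt$op == "=~"])
  var_free <- pt$op == "~~" & pt$lhs == pt$rhs & pt$free &
    pt$lhs %in% spec$observed
  if (any(var_free)) {
    v0 <- cv[pt$lhs[var_free]]
    halve <- pt$lhs[var_free] %in% has_loading
    start[pt$label[var_free]] <- ifelse(halve, 0.5 * v0, v0)
  }
  to_work <- function(th) { w <- th
    if (variance_scale == "log") w[is_var] <- log(pmax(th[is_var], 1e-4)); w }
  to_nat <- function(w) { th <- w
    if (variance_scale == "log") th[is_var] <- exp(w[is_var]); th }
  nll <- function(w) {
    th <- to_nat(w)
    mom <- tryCatch(implied_moments(spec, stats::setNames(th, labels)),
                    error = function(e) NULL)
    if (is.null(mom)) return(1e10)
    ll <- loglik_patterns(patterns, mom$mu, mom$Sigma)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ngr <- function(w) {
    th <- to_nat(w)
    g <- loglik_theta_gradient(spec, stats::setNames(th, labels), patterns)
    if (is.null(g)) return(rep(0, q))  # non-PD region: flat penalty plateau
    g <- -g
    if (variance_scale == "log") g[is_var] <- g[is_var] * th[is_var]
    g
  }

  # wide box bounds on regression slopes: solutions of interest lie well
  # inside, and the bounds stop runaway along weakly identified ridges
  reg_rows <- pt$op == "~" & pt$free
  is_reg <- labels %in% unique(pt$label[reg_rows])
  lower <- rep(-Inf, q); upper <- rep(Inf, q)
  lower[is_reg] <- -30; upper[is_reg] <- 30

  w0 <- to_work(start)
  starts <- list(w0)
  if (restarts > 0L) {
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- w0 + stats::runif(q, -jitter, jitter)
  }
  best <- NULL
  for (w in starts) {
    opt <- tryCatch(
      stats::nlminb(w, nll, gradient = ngr,
                    lower = lower, upper = upper,
                    control = list(iter.max = max_iterations,
                                   eval.max = 4L * max_iterations,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt$ok <- opt$convergence == 0L && opt$objective < 1e9
    if (is.null(best) ||
        (opt$ok && !best$ok) ||
        (opt$ok == best$ok && opt$objective < best$objective)) best <- opt
  }
  if (is.null(best)) stop("optimization failed for every start")
  w_hat <- best$par
  theta_hat <- stats::setNames(to_nat(w_hat), labels)
  loglik <- -best$objective
  sat <- fiml_saturated(Y)
  chi2 <- max(0, 2 * (sat$loglik - loglik))

  vcov_nat <- matrix(NA_real_, q, q, dimnames = list(labels, labels))
  se_nat <- stats::setNames(rep(NA_real_, q), labels)
  npd_param_vcov <- FALSE
  if (se && q > 0L) {
    H <- tryCatch(stats::optimHess(w_hat, nll, ngr), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
      npd_param_vcov <- any(ev < -1e-8 * max(abs(ev), 1))
      Vw <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vw)) {
        Jd <- rep(1, q)
        if (variance_scale == "log") Jd[is_var] <- theta_hat[is_var]
        vcov_nat <- diag(Jd, q) %*% Vw %*% diag(Jd, q)
        dimnames(vcov_nat) <- list(labels, labels)
        se_nat <- sqrt(pmax(diag(vcov_nat), 0))
        se_nat[diag(vcov_nat) < 0] <- NA_real_
      } else npd_param_vcov <- TRUE
    } else npd_param_vcov <- TRUE
  }

  mom_all <- implied_moments(spec, theta_hat, all = TRUE)
  lat <- spec$latents
  npd_latent_cov <- FALSE
  if (length(lat)) {
    evl <- eigen(mom_all$Sigma[lat, lat, drop = FALSE], symmetric = TRUE,
                 only.values = TRUE)$values
    npd_latent_cov <- any(evl < -1e-8 * max(abs(evl), 1))
  }

  heywood <- heywood_table(spec, theta_hat, se_nat)

  fit <- structure(list(
    spec = spec, theta = theta_hat, se = se_nat, vcov = vcov_nat,
    loglik = loglik, loglik_sat = sat$loglik, sat_mu = sat$mu,
    sat_Sigma = sat$Sigma, chi2 = chi2, df = df, n_used = n, p = p,
    converged = isTRUE(best$ok), opt_message = best$message,
    heywood = heywood, npd_param_vcov = npd_param_vcov,
    npd_latent_cov = npd_latent_cov, variance_scale = variance_scale,
    data = Y, restarts = restarts, jitter = jitter,
    Sigma_hat = implied_moments(spec, theta_hat)$Sigma,
    mu_hat = implied_moments(spec, theta_hat)$mu,
    Sigma_all = mom_all$Sigma), class = "wm_fit")
  fit$standardized <- standardized_solution(fit)
  fit
}

heywood_table <- function(spec, theta, se) {
  pt <- spec$ptable
  vr <- pt[pt$op == "~~" & pt$lhs == pt$rhs & pt$free, , drop = FALSE]
  if (!nrow(vr)) return(tibble::tibble(variable = character(),
                                       estimate = double(), p_value = double()))
  est <- theta[vr$label]
  neg <- est < 0
  if (!any(neg)) return(tibble::tibble(variable = character(),
                                       estimate = double(), p_value = double()))
  sev <- se[vr$label][neg]
  z <- est[neg] / sev
  tibble::tibble(variable = vr$lhs[neg], label = vr$label[neg],
                 estimate = unname(est[neg]),
                 p_value = unname(2 * stats::pnorm(-abs(z))))
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("wm_fit: n =", x$n_used, " loglik =", format(x$loglik),
      " chi2 =", format(x$chi2, digits = 5), " df =", x$df,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Standardized solution
#'
#' Rescales loadings, regressions and covariances to the correlation metric
#' using the model-implied standard deviations of all (observed and latent)
#' variables at the estimates.
#'
#' @param fit a `wm_fit`.
#' @return tibble with `lhs`, `op`, `rhs`, `est`, `est_std`.
#' @export
standardized_solution <- function(fit) {
  spec <- fit$spec
  pt <- spec$ptable
  sds <- sqrt(pmax(diag(fit$Sigma_all), 0))
  vals <- pt$value
  vals[pt$free] <- fit$theta[pt$label[pt$free]]
  std <- vals
  for (i in seq_len(nrow(pt))) {
    lhs <- pt$lhs[i]; rhs <- pt$rhs[i]
    std[i] <- switch(pt$op[i],
      "=~" = vals[i] * sds[lhs] / sds[rhs],   # loading: rhs = lambda * lhs
      "~"  = vals[i] * sds[rhs] / sds[lhs],
      "~~" = if (lhs == rhs) {
               if (sds[lhs] > 0) vals[i] / sds[lhs]^2 else NA_real_
             } else vals[i] / (sds[lhs] * sds[rhs]),
      "~1" = vals[i])
  }
  tibble::tibble(lhs = pt$lhs, op = pt$op, rhs = pt$rhs, free = pt$free,
                 label = pt$label, est = vals, est_std = std)
}

#' Tidy parameter estimates
#'
#' @param fit a `wm_fit`.
#' @return tibble of free parameters with estimates, standard errors, Wald z
#'   and p-values, and 95% confidence bounds.
#' @export
parameter_estimates <- function(fit) {
  labels <- names(fit$theta)
  est <- unname(fit$theta)
  se <- unname(fit$se[labels])
  z <- est / se
  tibble::tibble(label = labels, estimate = est, se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 ci_lower = est - 1.959964 * se,
                 ci_upper = est + 1.959964 * se)
}

# ---- negative-variance rule and admissibility --------------------------------

#' Apply the negative-variance handling rule
#'
#' For every free variance estimated negative whose raw-scale Wald test is
#' not significant (p >= alpha), the variance is fixed to 0 and the model is
#' refitted; this iterates to a fixpoint within `max_passes`. Variances that
#' are negative *and* significant are left free and flagged (a genuine
#' Heywood case that the analyst must confront).
#'
#' @param fit a `wm_fit` estimated with `variance_scale = "raw"` (the rule
#'   needs observable negative variances; a log-scale fit is refitted on the
#'   raw scale first).
#' @param alpha significance level for the Wald test (default 0.05).
#' @param max_passes iteration cap.
#' @param ... passed to [fit_wm_model()] for refits.
#' @return list with the final `fit`, the modified `spec`, `fixed` (labels
#'   fixed to zero), `flagged` (significant negative variances) and
#'   `passes`.
#' @export
apply_negative_variance_rule <- function(fit, alpha = 0.05, max_passes = 5L,
                                         ...) {
  spec <- fit$spec
  if (fit$variance_scale != "raw")
    fit <- fit_wm_model(spec, as.data.frame(fit$data), variance_scale = "raw",
                        ...)
  fixed <- character()
  for (pass in seq_len(max_passes)) {
    hw <- fit$heywood
    cand <- hw[is.na(hw$p_value) | hw$p_value >= alpha, , drop = FALSE]
    if (!nrow(cand)) {
      return(list(fit = fit, spec = spec, fixed = fixed,
                  flagged = hw$variable[!is.na(hw$p_value) &
                                          hw$p_value < alpha],
                  passes = pass - 1L))
    }
    pt <- spec$ptable
    hit <- pt$label %in% cand$label
    pt$free[hit] <- FALSE
    pt$value[hit] <- 0
    pt$label[hit] <- ""
    spec <- wm_model_spec(spec$observed, spec$latents, pt)
    fixed <- c(fixed, cand$label)
    fit <- fit_wm_model(spec, as.data.frame(fit$data),
                        variance_scale = "raw", ...)
  }
  warning("negative-variance rule did not reach a fixpoint within ",
          max_passes, " passes")
  list(fit = fit, spec = spec, fixed = fixed,
       flagged = fit$heywood$variable[!is.na(fit$heywood$p_value) &
                                        fit$heywood$p_value < alpha],
       passes = max_passes, failed = TRUE)
}

#' Admissibility verdict for a fitted model
#'
#' A solution is inadmissible — and excluded from model comparison — if the
#' optimizer did not converge, the parameter variance–covariance matrix is
#' not positive definite, or the implied covariance matrix of the latent
#' variables is not positive definite.
#'
#' @param fit a `wm_fit`.
#' @param tol eigenvalues below `-tol` count as negative.
#' @return list with `admissible` (logical) and `reasons` (character).
#' @export
check_validity <- function(fit, tol = 1e-8) {
  reasons <- character()
  if (!isTRUE(fit$converged)) reasons <- c(reasons, "non-convergence")
  if (isTRUE(fit$npd_param_vcov))
    reasons <- c(reasons, "parameter vcov not positive definite")
  lat <- fit$spec$latents
  if (length(lat)) {
    ev <- eigen(fit$Sigma_all[lat, lat, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev < -tol))
      reasons <- c(reasons, "latent covariance matrix not positive definite")
  }
  list(admissible = length(reasons) == 0L, reasons = reasons)
}
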