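#' Declarative structural equation model specifications
#'
#' A `wm_model_spec` describes a latent variable model as a parameter table
#' over three relations, following the conventions common to path-syntax
#' model languages:
#'
#' * `lhs =~ rhs` — a factor loading (latent `lhs` measured by `rhs`),
#' * `lhs ~ rhs`  — a regression of `lhs` on predictor `rhs`,
#' * `lhs ~~ rhs` — a (residual) variance (`lhs == rhs`) or covariance,
#' * `lhs ~1`     — an intercept / mean.
#'
#' Each row is either free (estimated) or fixed at `value`. Free rows carry a
#' `label`; rows sharing a label share one parameter (equality constraint),
#' which is how two-indicator latents are locally identified. Covariances not
#' present in the table are fixed to zero, so orthogonality between, e.g., a
#' general factor and hemisphere bifactors is expressed by the absence of a
#' free covariance row (builders add explicit `fixed(0)` rows for the salient
#' orthogonality constraints so they are visible in the table).
#'
#' The free parameter vector theta has one slot per unique free label, in
#' canonical order: loadings, then (co)variances, then regressions, then
#' intercepts, each in table order of first appearance.
#'
#' @param observed character vector of observed variable names, in order.
#' @param latents character vector of latent variable names (may be empty).
#' @param rows data frame with columns `lhs`, `op`, `rhs`, `free`, `value`,
#'   `label` (see [pt_row()]).
#' @return an object of class `wm_model_spec`.
#' @seealso [pt_row()], [implied_moments()], [serialize_model()]
#' @export
wm_model_spec <- function(observed, latents = character(), rows) {
  stopifnot(is.character(observed), length(observed) >= 1L,
            !anyDuplicated(c(observed, latents)))
  pt <- as.data.frame(rows, stringsAsFactors = FALSE)
  needed <- c("lhs", "op", "rhs", "free", "value", "label")
  stopifnot(all(needed %in% names(pt)))
  pt <- pt[, needed]
  vars <- c(observed, latents)
  bad <- setdiff(c(pt$lhs, pt$rhs[pt$op != "~1"]), vars)
  if (length(bad)) stop("unknown variable(s) in parameter table: ",
                        paste(unique(bad), collapse = ", "))
  if (!all(pt$op %in% c("=~", "~", "~~", "~1")))
    stop("unknown operator in parameter table")
  # canonical row order: loadings, (co)variances, regressions, intercepts
  op_rank <- match(pt$op, c("=~", "~~", "~", "~1"))
  pt <- pt[order(op_rank), , drop = FALSE]
  rownames(pt) <- NULL
  # auto-label any free row without a label
  auto <- pt$free & (is.na(pt$label) | pt$label == "")
  if (any(auto)) {
    pt$label[auto] <- paste0(".p", which(auto))
  }
  pt$label[!pt$free] <- ""
  spec <- structure(list(observed = observed, latents = latents, ptable = pt),
                    class = "wm_model_spec")
  spec$compiled <- compile_spec(spec)
  spec
}

#' Build one parameter-table row
#'
#' @param lhs,op,rhs the relation (see [wm_model_spec()]); `rhs` is ignored
#'   for intercepts (`op = "~1"`).
#' @param free logical; is the parameter estimated?
#' @param value start value if free, fixed value otherwise.
#' @param label equality-class label; free rows sharing a label share one
#'   parameter. Empty labels are auto-filled.
#' @export
pt_row <- function(lhs, op, rhs = lhs, free = TRUE, value = if (free) 0.5 else 0,
                   label = "") {
  data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
             label = label, stringsAsFactors = FALSE)
}

#' @export
print.wm_model_spec <- function(x, ...) {
  cat("wm_model_spec: ", length(x$observed), " observed, ",
      length(x$latents), " latent, ", n_free_params(x),
      " free parameters\n", sep = "")
  invisible(x)
}

# Precompute index maps so implied_moments() fills matrices without a row loop.
compile_spec <- function(spec) {
  pt <- spec$ptable
  vars <- c(spec$observed, spec$latents)
  k <- length(vars)
  li <- match(pt$lhs, vars)
  ri <- match(pt$rhs, vars)
  labels <- free_param_labels_(pt)
  # value vector index: free rows draw from theta, fixed rows from pt$value
  theta_ix <- ifelse(pt$free, match(pt$label, labels), NA_integer_)
  A_rows <- which(pt$op %in% c("=~", "~"))
  A_i <- ifelse(pt$op[A_rows] == "=~", ri[A_rows], li[A_rows])
  A_j <- ifelse(pt$op[A_rows] == "=~", li[A_rows], ri[A_rows])
  S_rows <- which(pt$op == "~~")
  M_rows <- which(pt$op == "~1")
  var_rows <- S_rows[pt$lhs[S_rows] == pt$rhs[S_rows]]
  list(vars = vars, k = k, labels = labels, theta_ix = theta_ix,
       A_rows = A_rows, A_idx = cbind(A_i, A_j),
       S_rows = S_rows, S_idx = cbind(li[S_rows], ri[S_rows]),
       S_idx_t = cbind(ri[S_rows], li[S_rows]),
       M_rows = M_rows, M_idx = li[M_rows],
       variance_labels = unique(pt$label[var_rows][pt$free[var_rows]]))
}

free_param_labels_ <- function(pt) unique(pt$label[pt$free])

#' Free parameters of a model specification
#'
#' @param spec a [wm_model_spec()].
#' @return `free_param_labels()`: character vector of labels in canonical
#'   order; `n_free_params()`: their count; `default_theta()`: named start
#'   values (first table entry per label).
#' @export
free_param_labels <- function(spec) spec$compiled$labels

#' @rdname free_param_labels
#' @export
n_free_params <- function(spec) length(spec$compiled$labels)

#' @rdname free_param_labels
#' @export
default_theta <- function(spec) {
  pt <- spec$ptable
  labels <- spec$compiled$labels
  stats::setNames(pt$value[match(labels, pt$label)], labels)
}

# labels of free pure-variance parameters (used for log-scale optimization)
variance_param_labels <- function(spec) spec$compiled$variance_labels

# Fill RAM-style matrices A (directed paths), S (symmetric covariances),
# m (means) from theta.
spec_matrices <- function(spec, theta) {
  cm <- spec$compiled
  if (length(theta) != length(cm$labels))
    stop("theta has length ", length(theta), ", expected ", length(cm$labels))
  pt <- spec$ptable
  vals <- pt$value
  vals[pt$free] <- theta[cm$theta_ix[pt$free]]
  k <- cm$k
  A <- matrix(0, k, k, dimnames = list(cm$vars, cm$vars))
  S <- matrix(0, k, k, dimnames = list(cm$vars, cm$vars))
  m <- stats::setNames(numeric(k), cm$vars)
  A[cm$A_idx] <- vals[cm$A_rows]
  S[cm$S_idx] <- vals[cm$S_rows]
  S[cm$S_idx_t] <- vals[cm$S_rows]
  m[cm$M_idx] <- vals[cm$M_rows]
  list(A = A, S = S, m = m)
}

#' Model-implied moments
#'
#' Computes the model-implied covariance matrix and mean vector of the
#' observed variables by standard covariance algebra: with all directed
#' relations collected in `A`, exogenous (co)variances in `S` and the
#' observed-variable selector `F`,
#' `Sigma = F (I - A)^-1 S (I - A)^-T F'` and `mu = F (I - A)^-1 m`.
#' Equality classes map one free parameter into several matrix cells.
#'
#' @param spec a [wm_model_spec()].
#' @param theta numeric vector of free parameters (canonical order); defaults
#'   to the spec's start values.
#' @param all logical; if `TRUE`, return moments over observed *and* latent
#'   variables (used for standardization and latent correlations).
#' @return list with `Sigma` and `mu`.
#' @export
implied_moments <- function(spec, theta = default_theta(spec), all = FALSE) {
  mats <- spec_matrices(spec, theta)
  k <- nrow(mats$A)
  IA <- diag(k) - mats$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("(I - A) is singular: the specification contains a cycle"))
  Sigma <- B %*% mats$S %*% t(B)
  mu <- drop(B %*% mats$m)
  dimnames(Sigma) <- dimnames(mats$A)
  names(mu) <- colnames(mats$A)
  if (!all) {
    Sigma <- Sigma[spec$observed, spec$observed, drop = FALSE]
    mu <- mu[spec$observed]
  }
  list(Sigma = Sigma, mu = mu)
}

#' Serialize / parse a model specification
#'
#' `serialize_model()` writes a spec to a plain-text path syntax with one
#' term per line: free parameters as `lhs =~ (label)*rhs`, fixed parameters
#' as `lhs =~ 0.5*rhs`; equality constraints appear as repeated labels.
#' Header lines record observed/latent order so the round trip is lossless.
#' `parse_model()` inverts it.
#'
#' @param spec a [wm_model_spec()].
#' @param text character scalar as produced by `serialize_model()`.
#' @return `serialize_model()`: a character scalar; `parse_model()`: a
#'   [wm_model_spec()].
#' @export
serialize_model <- function(spec) {
  pt <- spec$ptable
  rhs_name <- ifelse(pt$op == "~1", "1", pt$rhs)
  rhs_txt <- ifelse(pt$free,
                    paste0("(", pt$label, ")*", rhs_name),
                    paste0(format(pt$value, digits = 17, trim = TRUE),
                           "*", rhs_name))
  op_txt <- ifelse(pt$op == "~1", "~", pt$op)
  start_txt <- ifelse(pt$free,
                      paste0("  # start=", format(pt$value, digits = 17,
                                                  trim = TRUE)), "")
  paste0(c(paste0("%observed: ", paste(spec$observed, collapse = " ")),
           paste0("%latents: ", paste(spec$latents, collapse = " ")),
           paste0(pt$lhs, " ", op_txt, " ", rhs_txt, start_txt)),
         collapse = "\n")
}

#' @rdname serialize_model
#' @export
parse_model <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  hdr <- function(key) {
    ln <- grep(paste0("^%", key, ":"), lines, value = TRUE)
    out <- trimws(sub(paste0("^%", key, ":"), "", ln))
    if (!nzchar(out)) character() else strsplit(out, "\\s+")[[1]]
  }
  observed <- hdr("observed")
  latents <- hdr("latents")
  body <- lines[!grepl("^%", lines)]
  rows <- lapply(body, function(ln) {
    start <- NA_real_
    if (grepl("# start=", ln, fixed = TRUE)) {
      start <- as.numeric(sub(".*# start=", "", ln))
      ln <- sub("#.*$", "", ln)
    }
    m <- regmatches(ln, regexec("^\\s*(\\S+)\\s+(=~|~~|~)\\s+(.*\\S)\\s*$", ln))[[1]]
    if (length(m) != 4L) stop("cannot parse model line: ", ln)
    lhs <- m[2]; op <- m[3]; term <- m[4]
    if (grepl("^\\(", term)) {
      lab <- sub("^\\(([^)]*)\\)\\*.*$", "\\1", term)
      rhs <- sub("^\\([^)]*\\)\\*", "", term)
      free <- TRUE; val <- start
    } else if (grepl("\\*", term)) {
      val <- as.numeric(sub("\\*.*$", "", term))
      rhs <- sub("^[^*]*\\*", "", term)
      free <- FALSE; lab <- ""
    } else {
      rhs <- term; free <- TRUE; val <- start; lab <- ""
    }
    if (op == "~" && rhs == "1") { op <- "~1"; rhs <- lhs }
    pt_row(lhs, op, rhs, free = free, value = val, label = lab)
  })
  wm_model_spec(observed, latents, do.call(rbind, rows))
}

# Identify endogenous latents: latents that receive a directed path.
endogenous_latents <- function(spec) {
  pt <- spec$ptable
  inc <- c(pt$rhs[pt$op == "=~"], pt$lhs[pt$op == "~"])
  intersect(spec$latents, inc)
}
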