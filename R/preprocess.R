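#' Average tract-level values into functional cluster indicators
#'
#' Each of the 10 cluster indicators (5 bilateral systems x 2 hemispheres)
#' is the arithmetic mean of the subject's non-missing member tracts; a
#' subject with all member tracts missing gets a missing cluster value.
#'
#' @param tracts tibble with `subject_id`, `site` and one column per tract.
#' @param map cluster map as from [default_cluster_map()].
#' @return tibble with `subject_id`, `site` and 10 cluster columns named
#'   `<cluster>_<hemisphere>`.
#' @export
average_tracts_to_clusters <- function(tracts, map = default_cluster_map()) {
  meta <- intersect(c("subject_id", "site"), names(tracts))
  tract_cols <- setdiff(names(tracts), meta)
  unmapped <- setdiff(tract_cols, map$tract)
  if (length(unmapped))
    stop("tract column(s) not in the cluster map: ",
         paste(unmapped, collapse = ", "))
  out <- tracts[, meta, drop = FALSE]
  for (c in unique(map$cluster)) for (h in unique(map$hemisphere)) {
    members <- intersect(map$tract[map$cluster == c & map$hemisphere == h],
                         tract_cols)
    if (!length(members)) next
    out[[paste0(c, "_", h)]] <-
      rowMeans(tracts[, members, drop = FALSE], na.rm = TRUE)
  }
  for (j in setdiff(names(out), meta)) out[[j]][is.nan(out[[j]])] <- NA_real_
  tibble::as_tibble(out)
}

#' Cellwise outlier removal at k site-standard-deviations
#'
#' A value is set to missing when it deviates from its site's column mean by
#' more than `k` site standard deviations. Site statistics are computed once
#' on the raw values (a single discard pass, no re-estimation).
#'
#' @param table tibble with a `site` column and numeric value columns.
#' @param k threshold in SD units (default 3).
#' @return list with `table` (values masked) and `report` (per-column and
#'   overall removal fractions).
#' @export
remove_outliers <- function(table, k = 3) {
  stopifnot("site" %in% names(table))
  meta <- intersect(c("subject_id", "site"), names(table))
  cols <- setdiff(names(table), meta)
  removed <- 0L; total <- 0L
  per_col <- stats::setNames(numeric(length(cols)), cols)
  for (j in cols) {
    for (s in unique(table$site)) {
      ix <- which(table$site == s)
      x <- table[[j]][ix]
      mu <- mean(x, na.rm = TRUE); sd <- stats::sd(x, na.rm = TRUE)
      total <- total + sum(!is.na(x))
      if (!is.finite(sd) || sd == 0) {
        if (sum(!is.na(x)) > 1L)
          warning("zero SD in column ", j, " at site ", s, "; no removals")
        next
      }
      bad <- !is.na(x) & abs(x - mu) > k * sd
      table[[j]][ix[bad]] <- NA_real_
      removed <- removed + sum(bad)
      per_col[j] <- per_col[j] + sum(bad)
    }
  }
  list(table = table,
       report = list(removed = removed, cells = total,
                     fraction = if (total > 0) removed / total else 0,
                     per_column = per_col))
}

#' Two-sample z-standardization: within sites, then across the merged data
#'
#' Each column is centered and scaled within each site (missing values
#' ignored), the sites are merged, and the merged column is centered and
#' scaled again, so combined columns have mean 0 and SD 1 while site mean
#' differences are removed before pooling.
#'
#' @param table tibble with a `site` column and numeric value columns.
#' @return tibble of the same shape with standardized value columns.
#' @export
zstandardize_within_then_across <- function(table) {
  stopifnot("site" %in% names(table))
  meta <- intersect(c("subject_id", "site"), names(table))
  cols <- setdiff(names(table), meta)
  for (j in cols) {
    for (s in unique(table$site)) {
      ix <- which(table$site == s)
      x <- table[[j]][ix]
      nv <- sum(!is.na(x))
      if (nv < 2L) stop("column ", j, " has fewer than 2 values at site ", s)
      sd <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(sd) || sd == 0)
        stop("zero within-site SD for column ", j, " at site ", s)
      table[[j]][ix] <- (x - mean(x, na.rm = TRUE)) / sd
    }
    x <- table[[j]]
    table[[j]] <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  }
  table
}

#' Univariate normality screen
#'
#' Sample skewness `m3 / m2^(3/2)` and kurtosis per column; the kurtosis is
#' reported raw (non-excess, normal = 3) to match the conventional cutoff
#' pair (|skewness| >= 2, kurtosis >= 7); set `excess = TRUE` to report
#' excess kurtosis (the flag threshold is shifted accordingly).
#'
#' @param table tibble with numeric value columns (metadata columns
#'   `subject_id`/`site` ignored).
#' @param skew_threshold,kurtosis_threshold flag cutoffs.
#' @param excess report excess kurtosis instead of raw?
#' @return tibble with `variable`, `skewness`, `kurtosis`, `flagged`.
#' @export
screen_normality <- function(table, skew_threshold = 2, kurtosis_threshold = 7,
                             excess = FALSE) {
  cols <- setdiff(names(table), c("subject_id", "site"))
  rows <- lapply(cols, function(j) {
    x <- table[[j]]; x <- x[!is.na(x)]
    stopifnot(length(x) >= 3L)
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    sk <- m3 / m2^1.5
    ku <- m4 / m2^2 - if (excess) 3 else 0
    kth <- kurtosis_threshold - if (excess) 3 else 0
    tibble::tibble(variable = j, skewness = sk, kurtosis = ku,
                   flagged = abs(sk) >= skew_threshold | ku >= kth)
  })
  dplyr::bind_rows(rows)
}

#' Spearman-Brown step-up correction
#'
#' Reliability of the full-length test from the half-test correlation:
#' `2 r / (1 + r)`.
#'
#' @param r_half correlation between test halves, in (-1, 1].
#' @export
spearman_brown <- function(r_half) {
  stopifnot(is.numeric(r_half))
  if (any(r_half <= -1 | r_half > 1))
    stop("r_half must lie in (-1, 1]")
  2 * r_half / (1 + r_half)
}

#' Split-half reliability of a bilateral cluster
#'
#' Spearman-Brown-corrected Pearson correlation between the left- and
#' right-hemisphere cluster averages (pairwise complete observations).
#'
#' @param left,right numeric vectors of the two hemisphere averages.
#' @export
split_half_reliability <- function(left, right) {
  ok <- !is.na(left) & !is.na(right)
  stopifnot(sum(ok) >= 3L)
  if (stats::sd(left[ok]) == 0 || stats::sd(right[ok]) == 0)
    stop("zero variance in a hemisphere average")
  spearman_brown(stats::cor(left[ok], right[ok]))
}

#' Score the matrix-reasoning items and apply the chance-level exclusion
#'
#' Computes per-subject proportion correct overall and over odd- and
#' even-numbered items (1-based in administered order); missing responses
#' count as incorrect. Subjects scoring at or below the guessing chance
#' `1 / n_options` of their test form are excluded and reported.
#'
#' @param items long tibble with `subject_id`, `item`, `correct`, `n_items`,
#'   `n_options`.
#' @return list with `scores` (per retained subject: `prop_correct`,
#'   `gf_odd`, `gf_even`) and `excluded` (subject ids at or below chance).
#' @export
score_and_filter_intelligence <- function(items) {
  needed <- c("subject_id", "item", "correct", "n_items", "n_options")
  stopifnot(all(needed %in% names(items)))
  items$correct[is.na(items$correct)] <- 0L
  scores <- items |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_items = .data$n_items[1], n_options = .data$n_options[1],
      prop_correct = sum(.data$correct) / .data$n_items[1],
      gf_odd = sum(.data$correct[.data$item %% 2 == 1]) /
        sum(seq_len(.data$n_items[1]) %% 2 == 1),
      gf_even = sum(.data$correct[.data$item %% 2 == 0]) /
        sum(seq_len(.data$n_items[1]) %% 2 == 0),
      .groups = "drop")
  at_chance <- scores$prop_correct <= 1 / scores$n_options
  list(scores = scores[!at_chance, ], excluded = scores$subject_id[at_chance])
}

#' Partial correlations controlling for one variable
#'
#' Pearson correlations of the residuals after regressing each column on the
#' control variable. Columns with (residual) zero variance yield `NA`
#' entries and are flagged.
#'
#' @param table tibble of numeric columns (metadata columns ignored).
#' @param control numeric or factor vector, same length as `nrow(table)`.
#' @return list with `cor` (matrix) and `flagged` (column names with
#'   undefined entries).
#' @export
partial_correlations <- function(table, control) {
  cols <- setdiff(names(table), c("subject_id", "site"))
  stopifnot(length(control) == nrow(table),
            length(unique(control)) > 1L)
  res <- sapply(cols, function(j) {
    y <- table[[j]]
    r <- rep(NA_real_, length(y))
    ok <- !is.na(y)
    r[ok] <- stats::residuals(stats::lm(y ~ control, subset = ok))
    r
  })
  sds <- apply(res, 2L, stats::sd, na.rm = TRUE)
  flagged <- cols[!is.finite(sds) | sds < sqrt(.Machine$double.eps)]
  C <- suppressWarnings(stats::cor(res, use = "pairwise.complete.obs"))
  C[flagged, ] <- NA_real_; C[, flagged] <- NA_real_
  diag(C) <- 1
  list(cor = C, flagged = flagged)
}

#' Standardized cluster tables for analysis
#'
#' Convenience wrapper running the fixed preprocessing order on a marker
#' table: cellwise outlier removal on the raw (tract-level) values, averaging
#' of tracts into the 10 cluster indicators, then within-site
#' z-standardization, merging, and combined z-standardization of the cluster
#' columns. Permuting these stages changes the result; the order is part of
#' the analysis contract.
#'
#' @param table tract- or cluster-level marker table with `subject_id`,
#'   `site`.
#' @param map cluster map; set `NULL` if `table` is already cluster-level.
#' @param k outlier threshold in SD units.
#' @return list with the standardized `table` and the outlier `report`.
#' @export
preprocess_marker_table <- function(table, map = default_cluster_map(), k = 3) {
  out <- remove_outliers(table, k = k)
  tbl <- out$table
  if (!is.null(map)) tbl <- average_tracts_to_clusters(tbl, map)
  list(table = zstandardize_within_then_across(tbl),
       report = out$report)
}
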