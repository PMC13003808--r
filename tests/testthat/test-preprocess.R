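make_tract_table <- function(n = 6, seed = 1) {
  map <- default_cluster_map()
  set.seed(seed)
  M <- matrix(rnorm(n * 52), n, 52, dimnames = list(NULL, map$tract))
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                                  site = rep(c("A", "B"), length.out = n)),
                   tibble::as_tibble(M))
}

test_that("cluster averaging maps 52 tracts onto 10 indicators", {
  tbl <- make_tract_table()
  out <- average_tracts_to_clusters(tbl)
  expect_equal(setdiff(names(out), c("subject_id", "site")), wm_indicators())
  expect_equal(ncol(out) - 2L, 10L)

  # mean of constants: left arcuate tracts all 0.5
  map <- default_cluster_map()
  arc_l <- map$tract[map$cluster == "arcuate" & map$hemisphere == "L"]
  tbl[, arc_l] <- 0.5
  expect_equal(average_tracts_to_clusters(tbl)$arcuate_L, rep(0.5, 6))

  # two-member posterior ventral cluster: {0.4, 0.6} -> 0.5
  pv_l <- map$tract[map$cluster == "posterior_ventral" & map$hemisphere == "L"]
  expect_length(pv_l, 2L)  # uncinate + IFOF
  tbl[, pv_l[1]] <- 0.4; tbl[, pv_l[2]] <- 0.6
  expect_equal(average_tracts_to_clusters(tbl)$posterior_ventral_L, rep(0.5, 6))

  # missing members are dropped from the mean; all-missing stays missing
  tbl[1, pv_l[1]] <- NA
  expect_equal(average_tracts_to_clusters(tbl)$posterior_ventral_L[1], 0.6)
  tbl[1, pv_l] <- NA
  expect_true(is.na(average_tracts_to_clusters(tbl)$posterior_ventral_L[1]))

  names(tbl)[3] <- "mystery_tract"
  expect_error(average_tracts_to_clusters(tbl), "mystery_tract")
})

test_that("outlier masking uses single-pass site statistics", {
  tbl <- tibble::tibble(site = rep("A", 5), x = c(1, 2, 3, 4, 100),
                        const = 1)
  expect_warning(out <- remove_outliers(tbl), "zero SD")
  # small-sample masking: the 100 inflates the SD enough to survive 3 SD
  expect_equal(out$report$removed, 0L)
  expect_equal(out$table$x, tbl$x)

  # a clear outlier in a larger sample is masked
  tbl2 <- tibble::tibble(site = "A", x = c(rnorm(200), 50))
  out2 <- remove_outliers(tbl2)
  expect_true(is.na(out2$table$x[201]))
  expect_equal(out2$report$removed, sum(is.na(out2$table$x)))
})

test_that("injected extremes are removed at a plausible rate", {
  co <- small_cohort(seed = 7)
  rep_fa <- remove_outliers(co$tracts$FA)$report
  expect_gt(rep_fa$fraction, 0.001)
  expect_lt(rep_fa$fraction, 0.02)
})

test_that("within-then-across standardization meets its contracts", {
  tbl <- tibble::tibble(site = rep(c("A", "B"), c(40, 60)),
                        x = c(rnorm(40, 10, 2), rnorm(60, -5, 9)),
                        y = c(rnorm(40, 0, 1), rnorm(60, 3, 0.5)))
  z <- zstandardize_within_then_across(tbl)
  for (j in c("x", "y")) {
    expect_equal(mean(z[[j]]), 0, tolerance = 1e-10)
    expect_equal(sd(z[[j]]), 1, tolerance = 1e-10)
    expect_equal(as.vector(tapply(z[[j]], z$site, mean)), c(0, 0),
                 tolerance = 1e-10)
  }
  # single site degenerates to plain z-scoring
  one <- tibble::tibble(site = "A", x = rnorm(30, 5, 3))
  z1 <- zstandardize_within_then_across(one)
  expect_equal(z1$x, as.numeric(scale(one$x)) * sqrt(29 / 29), tolerance = 1e-10)
  # zero within-site SD errors with the column named
  bad <- tibble::tibble(site = rep(c("A", "B"), each = 3),
                        x = c(1, 1, 1, 1, 2, 3))
  expect_error(zstandardize_within_then_across(bad), "x.*site A|site A.*x")
})

test_that("the preprocessing stage order is part of the contract", {
  # an extreme value shifts the mean/SD; standardizing first would hide it
  set.seed(9)
  tbl <- tibble::tibble(site = "A", x = c(rnorm(150), 8))
  a <- zstandardize_within_then_across(remove_outliers(tbl)$table |>
                                         tidyr::drop_na())
  b <- remove_outliers(zstandardize_within_then_across(tbl))$table
  expect_false(isTRUE(all.equal(sd(a$x), sd(b$x, na.rm = TRUE))))
})

test_that("normality screening flags heavy skew and kurtosis", {
  set.seed(11)
  tbl <- tibble::tibble(normal = rnorm(1e4), expo = rexp(1e4),
                        twopoint = rep(c(-1, 1), 5e3))
  sc <- screen_normality(tbl)
  expect_false(sc$flagged[sc$variable == "normal"])
  expect_true(sc$flagged[sc$variable == "expo"])
  expect_equal(sc$skewness[sc$variable == "expo"], 2, tolerance = 0.4)
  expect_equal(sc$skewness[sc$variable == "twopoint"], 0, tolerance = 1e-12)
  # raw kurtosis of a normal is ~3; excess convention shifts by 3
  sc_ex <- screen_normality(tbl, excess = TRUE)
  expect_equal(sc_ex$kurtosis[sc_ex$variable == "normal"],
               sc$kurtosis[sc$variable == "normal"] - 3)
  expect_equal(sc$flagged, sc_ex$flagged)
})

test_that("Spearman-Brown correction has its closed-form values", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.5), 2 / 3, tolerance = 1e-12)
  expect_equal(spearman_brown(0), 0)
  expect_error(spearman_brown(-1), "r_half")
})

test_that("split-half reliability behaves at the extremes", {
  x <- rnorm(100)
  expect_equal(split_half_reliability(x, x), 1)
  set.seed(13)
  expect_equal(split_half_reliability(rnorm(1e4), rnorm(1e4)), 0,
               tolerance = 0.05)
  expect_error(split_half_reliability(rep(1, 10), rnorm(10)), "variance")
})

test_that("synthetic cluster reliabilities are high under default loadings", {
  co <- small_cohort(seed = 17)
  cl <- average_tracts_to_clusters(co$tracts$FA)
  for (c in wm_clusters()) {
    r <- split_half_reliability(cl[[paste0(c, "_L")]], cl[[paste0(c, "_R")]])
    expect_gt(r, 0.5)
  }
})

test_that("chance-level scoring excludes at the form-specific threshold", {
  mk_items <- function(id, n_items, n_options, n_correct) {
    idx <- seq_len(n_items)
    tibble::tibble(subject_id = id, item = idx,
                   n_items = n_items, n_options = n_options,
                   correct = as.integer(idx <= n_correct))
  }
  items <- dplyr::bind_rows(
    mk_items("s1", 48, 5, 9),    # 0.1875 <= 1/5 -> excluded
    mk_items("s2", 36, 8, 5),    # 0.139  >  1/8 -> retained
    mk_items("s3", 36, 8, 36))   # perfect score
  out <- score_and_filter_intelligence(items)
  expect_equal(out$excluded, "s1")
  expect_setequal(out$scores$subject_id, c("s2", "s3"))
  s3 <- out$scores[out$scores$subject_id == "s3", ]
  expect_equal(s3$gf_odd, 1); expect_equal(s3$gf_even, 1)
  # missing responses count as incorrect
  items$correct[items$subject_id == "s3" & items$item <= 2] <- NA
  out2 <- score_and_filter_intelligence(items)
  s3b <- out2$scores[out2$scores$subject_id == "s3", ]
  expect_equal(s3b$prop_correct, 34 / 36, tolerance = 1e-12)
})

test_that("partial correlations control for the nuisance variable", {
  # hand case: binary control -> within-group centering; residuals of
  # x=(1,2,3,4) and y=(1,2,4,3) given c=(0,0,1,1) are exactly orthogonal
  tbl <- tibble::tibble(x = c(1, 2, 3, 4), y = c(1, 2, 4, 3))
  out <- partial_correlations(tbl, control = c(0, 0, 1, 1))
  expect_equal(out$cor["x", "y"], 0, tolerance = 1e-12)

  # control uncorrelated with the columns: partial ~ raw correlation
  set.seed(19)
  n <- 1e4
  ctl <- rnorm(n); x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  tbl <- tibble::tibble(x = x, y = y)
  out <- partial_correlations(tbl, ctl)
  expect_equal(out$cor["x", "y"], cor(x, y), tolerance = 0.02)

  # y = x = control: zero residual variance, flagged
  tbl <- tibble::tibble(x = ctl, y = ctl)
  out <- partial_correlations(tbl, ctl)
  expect_setequal(out$flagged, c("x", "y"))
  expect_true(is.na(out$cor["x", "y"]))
})
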