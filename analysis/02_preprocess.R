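#!/usr/bin/env Rscript
# Stage 2 — preprocessing and descriptives.
#
# Outlier screen (+-3 site-SD, single pass), tract-to-cluster averaging,
# within-site z-standardization, merge, combined z-standardization;
# intelligence scoring with the chance-level exclusion; normality screen,
# split-half reliabilities and source-partialled correlations. Mirrors the
# descriptive stage of the analysis before any latent modeling.

suppressMessages({
  library(wmlatent)
  library(jsonlite)
})

cohort <- local({           # re-read the stage-1 CSVs through the schema
  dirp <- "results/cohort"
  stopifnot(dir.exists(dirp))
  markers <- c("FA", "INVF", "MTR")
  list(
    tracts = setNames(lapply(markers, function(m)
      tibble::as_tibble(utils::read.csv(file.path(dirp,
        paste0("tracts_", m, ".csv")), check.names = FALSE))), markers),
    items = tibble::as_tibble(utils::read.csv(file.path(dirp, "items.csv"))),
    demographics = tibble::as_tibble(
      utils::read.csv(file.path(dirp, "demographics.csv"))))
})

data <- prepare_analysis_data(cohort)
dir.create("results", showWarnings = FALSE)

for (m in names(data$clusters))
  utils::write.csv(data$clusters[[m]],
                   file.path("results", paste0("clusters_", m, ".csv")),
                   row.names = FALSE)

removal <- lapply(data$removal_reports, function(r)
  list(removed = r$removed, cells = r$cells, fraction = r$fraction))
write_json(removal, "results/removal_report.json", auto_unbox = TRUE,
           digits = NA)

cat("Outlier removal (fraction of cells):\n")
for (m in names(removal))
  cat(sprintf("  %-5s %.3f%%\n", m, 100 * removal[[m]]$fraction))
cat("Chance-level exclusions:", length(data$excluded_subjects), "\n")

# normality screen on the standardized cluster indicators
for (m in names(data$clusters)) {
  sc <- screen_normality(data$clusters[[m]])
  cat(sprintf("%s: max |skewness| %.2f, max kurtosis %.2f, %d flagged\n",
              m, max(abs(sc$skewness)), max(sc$kurtosis), sum(sc$flagged)))
}

# split-half reliabilities of the cluster averages (pre-standardization)
rel <- list()
for (m in names(cohort$tracts)) {
  cl <- average_tracts_to_clusters(cohort$tracts[[m]])
  rel[[m]] <- sapply(wm_clusters(), function(c)
    split_half_reliability(cl[[paste0(c, "_L")]], cl[[paste0(c, "_R")]]))
  cat(sprintf("%s split-half reliabilities: %.2f - %.2f\n",
              m, min(rel[[m]]), max(rel[[m]])))
}
write_json(rel, "results/reliability_report.json", digits = NA)

# partial correlations of FA and INVF indicators given data source
fa <- data$clusters$FA
demo <- data$demographics
joint <- merge(fa, data$clusters$INVF, by = c("subject_id", "site"),
               suffixes = c("_FA", "_INVF"))
ctl <- demo$source[match(joint$subject_id, demo$subject_id)]
pc <- partial_correlations(joint[, setdiff(names(joint),
                                           c("subject_id", "site"))], ctl)
utils::write.csv(round(pc$cor, 3), "results/partial_correlations.csv")
cat("Partial correlation matrix written (",
    nrow(pc$cor), "x", ncol(pc$cor), ")\n")
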