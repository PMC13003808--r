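# Shared loader for the analysis stages: re-reads the stage-1 cohort CSVs
# and runs the preprocessing chain once.
load_prepared <- function(dirp = "results/cohort") {
  stopifnot(dir.exists(dirp))
  markers <- c("FA", "INVF", "MTR")
  cohort <- list(
    tracts = stats::setNames(lapply(markers, function(m)
      tibble::as_tibble(utils::read.csv(file.path(dirp,
        paste0("tracts_", m, ".csv")), check.names = FALSE))), markers),
    items = tibble::as_tibble(utils::read.csv(file.path(dirp, "items.csv"))),
    demographics = tibble::as_tibble(
      utils::read.csv(file.path(dirp, "demographics.csv"))))
  prepare_analysis_data(cohort)
}
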