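#' Published telemetry sample sizes
#'
#' Per-PMU (population management unit), per-season counts of marked
#' sage-grouse and telemetry locations for the Nevada and northeastern
#' California study region, plus the region-wide classification/validation
#' subset sizes. These printed tables are inputs to the bookkeeping checks:
#' summing the per-site location counts reproduces the seasonal totals
#' (19,174 spring; 15,753 summer/fall; 9,926 winter; 44,853 overall), and
#' the screening rule can be evaluated against each site-season row.
#'
#' @return `pmu_season_counts()`: data frame with `pmu`, `season`,
#'   `n_birds`, `n_locs` and the `modeled` flag (site-seasons used to train
#'   RSFs). `study_sample_sizes()`: data frame with `subset`, `n_birds`,
#'   `n_locs` for the classification and the within/outside-RSF validation
#'   subsets.
#' @export
pmu_season_counts <- function() {
  utils::read.csv(system.file("extdata", "pmu_season_counts.csv",
                              package = "rsfmap"),
                  stringsAsFactors = FALSE)
}

#' @rdname pmu_season_counts
#' @export
study_sample_sizes <- function() {
  utils::read.csv(system.file("extdata", "study_sample_sizes.csv",
                              package = "rsfmap"),
                  stringsAsFactors = FALSE)
}
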