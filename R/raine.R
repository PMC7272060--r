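#' Published period-level survey summary for the Raine Island rookery
#'
#' Period-mean turtle counts and Lincoln-Petersen estimates (with standard
#' errors) for each survey method over the 2013--2017 nesting seasons at
#' Raine Island, as reported by the rookery's mark-resight monitoring
#' programme. These are period-level summaries (means over repeated
#' surveys, hence the fractional totals), not raw per-survey counts; they
#' are the inputs for between-method conversion factors and totals
#' comparisons.
#'
#' @return Tibble: `period_id`, `method`, `n_surveys`, `mean_total`,
#'   `n_hat`, `se`.
#' @seealso [raine_markings()], [conversion_factor()], [compare_totals()]
#' @export
raine_estimates <- function() {
  readr::read_csv(system.file("extdata", "raine_period_estimates.csv",
                              package = "markresight"),
                  show_col_types = FALSE,
                  col_types = "ccinnn")
}

#' Marked-cohort sizes per survey period at the Raine Island rookery
#'
#' Number of nesting females paint-marked on the single marking night of
#' each survey period (all suitable nesters up to a cap of 2000).
#'
#' @return Tibble: `period_id`, `n_marked`.
#' @export
raine_markings <- function() {
  readr::read_csv(system.file("extdata", "raine_markings.csv",
                              package = "markresight"),
                  show_col_types = FALSE, col_types = "ci")
}
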