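#' Published range-accounting inputs for the dove tree
#'
#' The km2 suitable-area accounting published for *Davidia involucrata*
#' (dove tree) across thirteen climate scenarios: the present, three
#' mid-Holocene and three Last Glacial Maximum hindcasts, and six 2070
#' forecasts (three general circulation models under RCP 2.6 and RCP 8.5).
#' Columns give, per scenario, the total suitable area, its low
#' (threshold-0.5) and high (0.5-1) suitability bands, and the overlap with
#' the present-day suitable area, all in km2.  Every published derived
#' percentage and period average can be recomputed from these inputs with
#' [scenario_table()], which is how the package validates its range
#' accounting arithmetic.
#'
#' @return data frame with columns `model`, `period`, `total_km2`,
#'   `low_km2`, `high_km2`, `overlap_km2`.
#' @export
davidia_range_table <- function() {
  utils::read.csv(system.file("extdata", "davidia_range_table.csv",
                              package = "maxsdm"),
                  stringsAsFactors = FALSE)
}
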