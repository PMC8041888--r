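#' Bundled national reporting tables for Bangladesh TOF
#'
#' Small CSV/JSON fixtures shipped with the package: the published
#' per-division TOF areas with 95% CIs (`table1`), the national patch-size
#' distribution counts (`table2`), the per-division comparison areas against
#' a cover-derived extent map and a radar forest/non-forest (FNF) product
#' (`table3`), and scalar reference constants (national forest area,
#' population, campaign sizes). These are the printed *inputs* that the
#' accounting layer reproduces arithmetic from; they are not computed by
#' this package.
#'
#' @return list with data.frames `table1`, `table2`, `table3` and list
#'   `constants`.
#' @export
tof_reference_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "tofscape",
                               mustWork = TRUE)
  list(table1 = utils::read.csv(p("table1_divisions.csv")),
       table2 = utils::read.csv(p("table2_patch_counts.csv"),
                                check.names = FALSE),
       table3 = utils::read.csv(p("table3_map_comparison.csv")),
       constants = jsonlite::read_json(p("reference_constants.json"),
                                       simplifyVector = TRUE))
}
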