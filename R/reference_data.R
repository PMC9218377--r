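# Access to the bundled summary tables of a published 345-accession East
# African sorghum diversity panel (341 unreplicated landrace/breeding-line
# tests plus 4 released checks, evaluated in a 22-block x 20-plot augmented
# design at two Ugandan locations). The raw plot data of that panel are not
# public; these printed summaries seed the simulator's defaults and allow
# the derived statistics to be recomputed from in-table inputs:
#   components   - trait means and variance components (13 quantitative
#                  traits, 2 environments)
#   qualitative  - descriptor class proportions (10 qualitative traits,
#                  percent of 345 accessions)
#   yield_panel  - grain yield of the top-ranked entries and the 4 checks
#   micronutrient_panel - grain Fe/Zn (ppm) of the nutrient-dense entries
#                  and the checks

#' Bundled sorghum diversity-panel summary tables
#'
#' @param table One of `"components"`, `"qualitative"`, `"yield_panel"`,
#'   `"micronutrient_panel"`.
#' @return The requested table as a data frame.
#' @export
sorghum_reference <- function(table = c("components", "qualitative",
                                        "yield_panel",
                                        "micronutrient_panel")) {
  table <- match.arg(table)
  file <- switch(table,
    components = "sorghum_trait_components.csv",
    qualitative = "sorghum_qualitative_classes.csv",
    yield_panel = "sorghum_yield_panel.csv",
    micronutrient_panel = "sorghum_micronutrient_panel.csv")
  path <- system.file("extdata", file, package = "augtrial",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Qualitative class proportions as named vectors
#'
#' @param n_total Panel size used to convert percentages into proportions
#'   (the proportions are renormalized to sum to exactly 1).
#' @return Named list, one numeric proportion vector per trait.
#' @export
sorghum_class_proportions <- function(n_total = 345) {
  q <- sorghum_reference("qualitative")
  out <- lapply(split(q, q$trait), function(d) {
    p <- d$proportion_pct / sum(d$proportion_pct)
    stats::setNames(p, d$category)
  })
  out[unique(q$trait)]
}
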