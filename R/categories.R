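#' Midpoint impact categories
#'
#' Registry of the eight midpoint impact categories the pipeline reports,
#' following the Product Environmental Footprint (PEF) midpoint set used for
#' dairy: climate change, land use, water use, fossil resource use, terrestrial
#' and freshwater acidification, and freshwater / marine / terrestrial
#' eutrophication.
#'
#' Eutrophication factors are stored internally in g P eq and g N eq (the units
#' upstream inventories print per kg of product); `display_scale` converts a
#' stored per-kg-FPCM value to the scale conventionally reported for milk
#' (kg-based for freshwater and marine eutrophication).
#'
#' @return A data frame with one row per category: `key` (stable identifier),
#'   `label` (long name), `unit` (reporting unit per kg FPCM), and
#'   `display_scale` (multiplier from internal storage units to `unit`).
#' @export
#' @examples
#' impact_categories()
impact_categories <- function() {
  data.frame(
    key = c("CC", "LU", "WU", "RU", "TFWAC", "FEU", "MEU", "TEU"),
    label = c(
      "climate change", "land use", "water use", "resource use (fossil)",
      "terrestrial and freshwater acidification",
      "freshwater eutrophication", "marine eutrophication",
      "terrestrial eutrophication"
    ),
    unit = c(
      "kg CO2 eq", "Pt", "m3 depriv eq", "MJ", "mol H+ eq",
      "kg P eq", "kg N eq", "mol N eq"
    ),
    # FEU/MEU stored in g P eq / g N eq, reported kg-based
    display_scale = c(1, 1, 1, 1, 1, 1e-3, 1e-3, 1),
    stringsAsFactors = FALSE
  )
}

#' @rdname impact_categories
#' @export
category_keys <- function() impact_categories()$key

# Source rows of the contribution breakdown, in report order.
source_keys <- function() {
  c("feed_compounds", "roughages", "on_farm_co2", "on_farm_n2o",
    "on_farm_ch4", "energy", "water", "additive", "luc")
}

source_labels <- function() {
  c(
    feed_compounds = "Feed compounds",
    roughages      = "Roughages",
    on_farm_co2    = "On farm CO2",
    on_farm_n2o    = "On-farm N2O",
    on_farm_ch4    = "On farm CH4",
    energy         = "Energy at Farm",
    water          = "Water at Farm",
    additive       = "Additive",
    luc            = "Land use change"
  )
}
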