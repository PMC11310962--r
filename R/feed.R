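#' Upstream feed-chain impacts per cow-year
#'
#' Impacts of compound feed, roughages, the additive, and land-use-change
#' adders per cow-year, from the emission-factor table. With a diet present,
#' each ingredient contributes `fi_annual x share x EF`, split into compound
#' and roughage rows by its `is_roughage` flag; without one, the system's
#' `compound_share` splits total intake between the generic `compound_feed`
#' and `roughage` items. Land-use change is a dedicated per-kg-intake adder
#' item, and the additive contributes `additive_mass_annual x EF(additive)`.
#'
#' @param profile An [annual_profile()][annualize()].
#' @param ef An [ef_table()].
#' @param diet Optional [diet()].
#' @param compound_share Compound-feed share of intake when no diet is given.
#' @param item_map Named character vector mapping the roles `compound`,
#'   `roughage`, `luc`, `additive` to EF-table item keys.
#' @return An object of class `feed_footprint`: matrix with rows
#'   `compound_feed`, `roughages`, `additive`, `luc` and one column per
#'   impact category, impact units per cow-year.
#' @export
feed_impacts <- function(profile, ef, diet = NULL, compound_share = 0.4,
                         item_map = default_item_map()) {
  stopifnot(inherits(profile, "annual_profile"), inherits(ef, "ef_table"))
  cats <- category_keys()
  out <- matrix(0, nrow = 4, ncol = length(cats),
                dimnames = list(c("compound_feed", "roughages", "additive", "luc"), cats))

  if (!is.null(diet)) {
    missing <- setdiff(diet$ingredient_key, unique(ef$item_key))
    if (length(missing)) {
      stop_resolution(sprintf("unresolved diet ingredient(s): %s",
                              paste(missing, collapse = ", ")), keys = missing)
    }
    for (i in seq_len(nrow(diet))) {
      qty <- profile$fi_annual * diet$share[i]
      row <- if (diet$is_roughage[i]) "roughages" else "compound_feed"
      for (cat in cats) {
        out[row, cat] <- out[row, cat] +
          qty * ef_factor(ef, diet$ingredient_key[i], cat, default = 0)
      }
    }
  } else {
    for (cat in cats) {
      out["compound_feed", cat] <- profile$fi_annual * compound_share *
        ef_factor(ef, item_map[["compound"]], cat, default = 0)
      out["roughages", cat] <- profile$fi_annual * (1 - compound_share) *
        ef_factor(ef, item_map[["roughage"]], cat, default = 0)
    }
  }
  for (cat in cats) {
    out["luc", cat] <- profile$fi_annual *
      ef_factor(ef, item_map[["luc"]], cat, default = 0)
    out["additive", cat] <- profile$additive_mass_annual *
      ef_factor(ef, item_map[["additive"]], cat, default = 0)
  }
  structure(out, class = c("feed_footprint", class(out)))
}

#' Economic allocation shares at crop level
#'
#' `share_i = mass_i x price_i / sum_j mass_j x price_j`; used when deriving
#' synthetic emission-factor rows from crop-process descriptions. Shares sum
#' to 1 exactly and are invariant under permutation of the coproducts.
#'
#' @param mass Coproduct masses (any common unit).
#' @param price Coproduct prices per unit mass; total value must be > 0.
#' @return Numeric vector of allocation shares, same order as inputs.
#' @export
#' @examples
#' economic_allocation(c(60, 40), c(2, 1))  # 0.75, 0.25
economic_allocation <- function(mass, price) {
  check_fields(list(
    mass = is.numeric(mass) && length(mass) >= 1 && all(is.finite(mass)) && all(mass >= 0),
    price = is.numeric(price) && length(price) == length(mass) &&
      all(is.finite(price)) && all(price >= 0)
  ), "economic_allocation")
  value <- mass * price
  total <- sum(value)
  if (total <= 0) {
    stop_validation("economic_allocation: total coproduct value is zero",
                    fields = "price")
  }
  value / total
}
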