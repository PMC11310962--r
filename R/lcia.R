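#' Characterization factors for on-farm flows
#'
#' Midpoint factors mapping on-farm emission flows into impact categories:
#' GWP100 for methane and nitrous oxide into climate change, ammonia into
#' acidification and terrestrial eutrophication, leached nitrogen into marine
#' eutrophication, excreted phosphorus into freshwater eutrophication.
#' Climate defaults are the AR6 GWP100 values (biogenic CH4 27.0, N2O 273);
#' the acidification/eutrophication magnitudes follow PEF-style midpoint
#' conventions. All are configurable — absolute category totals depend on the
#' factor vintage.
#'
#' @param gwp_ch4 GWP100 of biogenic methane, kg CO2 eq/kg.
#' @param gwp_n2o GWP100 of nitrous oxide, kg CO2 eq/kg.
#' @param gwp_co2 GWP100 of carbon dioxide (identity).
#' @param nh3_tfwac Acidification factor of NH3, mol H+ eq/kg.
#' @param nh3_teu Terrestrial eutrophication factor of NH3, mol N eq/kg.
#' @param n_leach_meu Marine eutrophication factor of leached N, g N eq/kg N.
#' @param p_excreted_feu Freshwater eutrophication factor of excreted P
#'   reaching freshwater, g P eq/kg P.
#' @param p_excretion_per_fi Phosphorus reaching freshwater per kg DM intake,
#'   kg P/kg DM (net of field retention).
#' @return An object of class `characterization_factors`.
#' @export
characterization_factors <- function(gwp_ch4 = 27.0, gwp_n2o = 273,
                                     gwp_co2 = 1,
                                     nh3_tfwac = 3.02, nh3_teu = 13.0,
                                     n_leach_meu = 1000,
                                     p_excreted_feu = 1000,
                                     p_excretion_per_fi = 0) {
  check_fields(list(
    gwp_ch4 = is_nonneg1(gwp_ch4), gwp_n2o = is_nonneg1(gwp_n2o),
    gwp_co2 = is_nonneg1(gwp_co2),
    nh3_tfwac = is_nonneg1(nh3_tfwac), nh3_teu = is_nonneg1(nh3_teu),
    n_leach_meu = is_nonneg1(n_leach_meu),
    p_excreted_feu = is_nonneg1(p_excreted_feu),
    p_excretion_per_fi = is_nonneg1(p_excretion_per_fi)
  ), "characterization_factors")
  structure(as.list(environment()), class = "characterization_factors")
}

#' Biophysical milk/meat allocation factor
#'
#' `AF = 1 - 6.04 x Mmeat / Mmilk`, the dairy-sector biophysical split between
#' milk and the meat coproducts (live weight of all animals sold). `Mmilk` is
#' the annual mass of fat- and protein-corrected milk sold. The meat share is
#' the complement `AM = 1 - AF`. The formula collapses (AF <= 0) when the
#' meat/milk ratio reaches 1/6.04.
#'
#' @param m_meat Live weight of animals sold, kg/yr.
#' @param m_milk_fpcm FPCM sold, kg/yr; must be > 0.
#' @return The milk allocation factor, in (0, 1].
#' @export
#' @examples
#' allocation_factor(200, 10000)  # 0.8792
allocation_factor <- function(m_meat, m_milk_fpcm) {
  check_fields(list(m_meat = is_nonneg1(m_meat)), "allocation_factor")
  if (!is_num1(m_milk_fpcm) || m_milk_fpcm <= 0) {
    stop_validation("allocation_factor: m_milk_fpcm must be > 0", fields = "m_milk_fpcm")
  }
  af <- 1 - 6.04 * m_meat / m_milk_fpcm
  if (af <= 0) {
    stop_numerical(sprintf(
      "allocation collapse: 6.04 x Mmeat/Mmilk = %.3f >= 1 leaves no burden on milk",
      6.04 * m_meat / m_milk_fpcm
    ))
  }
  af
}

#' Characterize flows into per-kg-FPCM impact results
#'
#' Builds the full source-by-category breakdown: feed-chain rows from the
#' feed footprint, on-farm CH4/N2O/CO2 rows from the emission flows via the
#' characterization factors, everything multiplied by the milk allocation
#' factor and divided by annual FPCM. The category total equals the column sum
#' of its breakdown by construction.
#'
#' @param flows An [emission_flows()].
#' @param feed A [feed_impacts()] matrix.
#' @param cf A [characterization_factors()].
#' @param profile An [annual_profile()][annualize()].
#' @param af Milk allocation factor in (0, 1].
#' @param ref Optional [reference_system()] supplying utility quantities for
#'   the energy/water rows (their upstream impacts per category).
#' @param ef Optional [ef_table()] for the energy/water upstream rows.
#' @param item_map Optional utility-name to item-key map (see [farm_system()]).
#' @return An object of class `impact_result`: list with `breakdown` (9
#'   sources x 8 categories, impact units per kg FPCM), `total` (per
#'   category), `af`, `fpcm_annual`, `ch4_provenance`.
#' @export
characterize <- function(flows, feed, cf, profile, af, ref = NULL, ef = NULL,
                         item_map = NULL) {
  stopifnot(inherits(flows, "emission_flows"),
            inherits(cf, "characterization_factors"),
            inherits(profile, "annual_profile"))
  if (profile$fpcm_annual <= 0) {
    stop_numerical("characterize: annual FPCM must be > 0 (functional unit)")
  }
  if (!is_num1(af) || af <= 0 || af > 1) {
    stop_validation("characterize: af must be in (0, 1]", fields = "af")
  }
  cats <- category_keys()
  src <- source_keys()
  bd <- matrix(0, nrow = length(src), ncol = length(cats),
               dimnames = list(src, cats))

  # feed-chain rows (already per cow-year, all categories)
  bd["feed_compounds", ] <- feed["compound_feed", cats]
  bd["roughages", ] <- feed["roughages", cats]
  bd["additive", ] <- feed["additive", cats]
  bd["luc", ] <- feed["luc", cats]

  # on-farm gas flows
  bd["on_farm_ch4", "CC"] <- (flows$ch4_enteric + flows$ch4_manure) * cf$gwp_ch4
  bd["on_farm_n2o", "CC"] <- (flows$n2o_direct + flows$n2o_indirect) * cf$gwp_n2o
  bd["on_farm_n2o", "TFWAC"] <- flows$nh3 * cf$nh3_tfwac
  bd["on_farm_n2o", "TEU"] <- flows$nh3 * cf$nh3_teu
  bd["on_farm_n2o", "MEU"] <- flows$n_leached * cf$n_leach_meu
  bd["on_farm_n2o", "FEU"] <- profile$fi_annual * cf$p_excretion_per_fi *
    cf$p_excreted_feu
  bd["on_farm_co2", "CC"] <- flows$co2_direct * cf$gwp_co2

  # purchased-utility rows, per category
  if (!is.null(ref) && !is.null(ef)) {
    u <- ref$utilities
    if (is.null(item_map)) item_map <- default_item_map(names(u))
    for (cat in cats) {
      if ("energy" %in% names(u)) {
        bd["energy", cat] <- u[["energy"]] *
          ef_factor(ef, item_map[["energy"]], cat, default = 0)
      }
      if ("water" %in% names(u)) {
        bd["water", cat] <- u[["water"]] *
          ef_factor(ef, item_map[["water"]], cat, default = 0)
      }
    }
  }

  bd <- bd * af / profile$fpcm_annual
  structure(list(
    breakdown = bd,
    total = colSums(bd),
    af = af,
    fpcm_annual = profile$fpcm_annual,
    ch4_provenance = flows$ch4_provenance
  ), class = "impact_result")
}

#' Assemble an impact result from a known breakdown
#'
#' Constructs an `impact_result` directly from per-kg-FPCM source
#' contributions — e.g. a published contribution table — so that comparison
#' and contribution analysis can run on reported values as well as modeled
#' ones.
#'
#' @param breakdown Matrix (sources x categories) or named vector (sources,
#'   single category) of per-kg-FPCM contributions.
#' @param category Category key when `breakdown` is a vector.
#' @param af Allocation factor bookkeeping (default 1).
#' @param fpcm_annual Annual FPCM bookkeeping (default `NA`).
#' @return An `impact_result`.
#' @export
impact_result <- function(breakdown, category = "CC", af = 1, fpcm_annual = NA_real_) {
  cats <- category_keys()
  src <- source_keys()
  if (is.matrix(breakdown)) {
    bd <- matrix(0, length(src), length(cats), dimnames = list(src, cats))
    bd[rownames(breakdown), colnames(breakdown)] <- breakdown
  } else {
    stopifnot(!is.null(names(breakdown)), category %in% cats)
    bd <- matrix(0, length(src), length(cats), dimnames = list(src, cats))
    bd[names(breakdown), category] <- breakdown
  }
  if (any(bd < 0)) stop_validation("impact_result: negative contribution", fields = "breakdown")
  structure(list(breakdown = bd, total = colSums(bd), af = af,
                 fpcm_annual = fpcm_annual, ch4_provenance = "reported"),
            class = "impact_result")
}

#' Contribution analysis
#'
#' Decomposes a category total into per-source percentage shares,
#' `100 x breakdown_i / total`; shares sum to 100 and are invariant under
#' rescaling all flows.
#'
#' @param result An [impact_result()].
#' @param category Impact-category key (default `"CC"`).
#' @return Named numeric vector of percentages, one per source row.
#' @export
contribution_analysis <- function(result, category = "CC") {
  stopifnot(inherits(result, "impact_result"))
  total <- result$total[[category]]
  if (!is.finite(total) || total <= 0) {
    stop_numerical(sprintf("contribution_analysis: %s total is not positive", category))
  }
  100 * result$breakdown[, category] / total
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("<impact_result> AF = %.4f, FPCM = %.1f kg/yr, CH4: %s\n",
              x$af, x$fpcm_annual, x$ch4_provenance))
  print(round(rbind(x$breakdown, Total = x$total), 4))
  invisible(x)
}
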