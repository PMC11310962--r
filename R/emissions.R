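#' On-farm emission model parameters
#'
#' IPCC Tier-2 parameters for enteric and manure methane, nitrogen excretion
#' and nitrous oxide, plus inventory-guidebook-style per-head factors for
#' ammonia-independent air pollutants. Defaults follow the Tier-2 dairy
#' conventions (Ym 6.5% of gross energy, 55.65 MJ/kg CH4, 0.67 kg/m3 CH4
#' density); every value is configurable.
#'
#' `ch4_scale` and `n2o_scale` are whole-system calibration multipliers: a
#' per-lactating-cow model understates (or, for nitrogen, mis-states) the
#' reference farm's herd-level flows (dry cows, youngstock, manure handling
#' chain), and fixture calibration absorbs that structure here rather than in
#' the biological constants.
#'
#' @param ym Methane conversion factor, % of gross energy intake emitted as
#'   enteric CH4, in (0, 15).
#' @param ch4_energy_density Energy content of methane, MJ/kg.
#' @param digestibility Digestible fraction of gross energy.
#' @param ash_fraction Ash fraction of manure organic matter.
#' @param urinary_energy_fraction Urinary energy as a fraction of GE.
#' @param ge_per_kg_dm Gross energy density used by the volatile-solids model,
#'   MJ/kg DM.
#' @param b0 Maximum methane-producing capacity of manure, m3 CH4/kg VS.
#' @param mcf Methane conversion factor of the manure system, fraction.
#' @param ch4_density Density of methane, kg/m3.
#' @param cp_fraction Crude-protein fraction of dietary DM (nitrogen route
#'   N = CP/6.25 when no nitrogen intake is supplied).
#' @param n_intake_annual Optional direct nitrogen intake, kg N/cow/yr,
#'   overriding the crude-protein route.
#' @param n_retention_fraction Fraction of intake nitrogen retained in milk
#'   and tissue.
#' @param ef3 Direct N2O emission factor, kg N2O-N per kg N excreted.
#' @param frac_gas Fraction of excreted N volatilized as NH3/NOx.
#' @param ef4 Indirect N2O factor for volatilized N, kg N2O-N/kg N.
#' @param frac_leach Fraction of excreted N leached.
#' @param ef5 Indirect N2O factor for leached N, kg N2O-N/kg N.
#' @param nh3_ef Optional per-head NH3 factor, kg/cow/yr, overriding the
#'   volatilization route.
#' @param nmvoc_ef,pm10_ef,pm25_ef Per-head air-pollutant factors, kg/cow/yr.
#' @param ch4_scale,n2o_scale Whole-system scaling of the CH4 and N2O flows.
#'
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(ym = 6.5, ch4_energy_density = 55.65,
                            digestibility = 0.70, ash_fraction = 0.08,
                            urinary_energy_fraction = 0.04,
                            ge_per_kg_dm = 18.45,
                            b0 = 0.24, mcf = 0.17, ch4_density = 0.67,
                            cp_fraction = 0.16, n_intake_annual = NULL,
                            n_retention_fraction = 0.25,
                            ef3 = 0.02, frac_gas = 0.30, ef4 = 0.01,
                            frac_leach = 0.30, ef5 = 0.0075,
                            nh3_ef = NULL, nmvoc_ef = 17.937,
                            pm10_ef = 1.15, pm25_ef = 0.75,
                            ch4_scale = 1, n2o_scale = 1) {
  check_fields(list(
    ym = is_num1(ym) && ym > 0 && ym < 15,
    ch4_energy_density = is_pos1(ch4_energy_density),
    digestibility = is_frac1(digestibility),
    ash_fraction = is_frac1(ash_fraction),
    urinary_energy_fraction = is_frac1(urinary_energy_fraction),
    ge_per_kg_dm = is_pos1(ge_per_kg_dm),
    b0 = is_nonneg1(b0),
    mcf = is_frac1(mcf),
    ch4_density = is_pos1(ch4_density),
    cp_fraction = is_frac1(cp_fraction),
    n_intake_annual = is.null(n_intake_annual) || is_nonneg1(n_intake_annual),
    n_retention_fraction = is_frac1(n_retention_fraction),
    ef3 = is_frac1(ef3), frac_gas = is_frac1(frac_gas), ef4 = is_frac1(ef4),
    frac_leach = is_frac1(frac_leach), ef5 = is_frac1(ef5),
    nh3_ef = is.null(nh3_ef) || is_nonneg1(nh3_ef),
    nmvoc_ef = is_nonneg1(nmvoc_ef),
    pm10_ef = is_nonneg1(pm10_ef), pm25_ef = is_nonneg1(pm25_ef),
    ch4_scale = is_pos1(ch4_scale), n2o_scale = is_pos1(n2o_scale)
  ), "emission_params")
  structure(as.list(environment()), class = "emission_params")
}

#' Enteric methane (Tier 2)
#'
#' `CH4 = GE x (Ym/100) / energy density of methane`. When a trial carries a
#' measured daily methane emission, the measurement overrides the model within
#' the trial window and the model covers the remaining gross energy; the
#' returned value carries a `provenance` attribute saying which route was used.
#'
#' @param ge_annual Gross energy intake, MJ/cow/yr.
#' @param params An [emission_params()].
#' @param measured_daily Optional measured CH4, kg/cow/d, applying to
#'   `measured_days`.
#' @param measured_days Days covered by the measurement.
#' @param ge_measured_window Gross energy intake within the measured window,
#'   MJ; subtracted from the modeled energy when a measurement is present.
#' @return Enteric CH4, kg/cow/yr, with attribute `provenance` equal to
#'   `"model"` or `"measured+model"`.
#' @export
enteric_ch4 <- function(ge_annual, params = emission_params(),
                        measured_daily = NULL, measured_days = 0,
                        ge_measured_window = 0) {
  check_fields(list(ge_annual = is_nonneg1(ge_annual)), "enteric_ch4")
  if (is.null(measured_daily)) {
    out <- ge_annual * (params$ym / 100) / params$ch4_energy_density
    return(structure(out, provenance = "model"))
  }
  ge_model <- max(ge_annual - ge_measured_window, 0)
  out <- measured_daily * measured_days +
    ge_model * (params$ym / 100) / params$ch4_energy_density
  structure(out, provenance = "measured+model")
}

#' Volatile-solids excretion
#'
#' IPCC form on gross energy: undigested plus urinary energy, mineral fraction
#' removed, converted to mass at the diet's energy density:
#' `VS = GE x ((1 - DE) + UE) x (1 - ash) / (MJ per kg DM)`.
#'
#' @inheritParams enteric_ch4
#' @return Volatile solids excreted, kg/cow/yr.
#' @export
volatile_solids <- function(ge_annual, params = emission_params()) {
  check_fields(list(ge_annual = is_nonneg1(ge_annual)), "volatile_solids")
  ge_annual * ((1 - params$digestibility) + params$urinary_energy_fraction) *
    (1 - params$ash_fraction) / params$ge_per_kg_dm
}

#' Manure methane (Tier 2)
#'
#' `CH4 = VS x B0 x 0.67 x MCF` with the manure system's methane conversion
#' factor.
#'
#' @param vs Volatile solids excreted, kg/cow/yr (see [volatile_solids()]).
#' @param params An [emission_params()].
#' @param manure_system_label Manure system label; required (the MCF is
#'   meaningless without one).
#' @return Manure CH4, kg/cow/yr.
#' @export
manure_ch4 <- function(vs, params = emission_params(),
                       manure_system_label = "liquid_slurry") {
  check_fields(list(vs = is_nonneg1(vs)), "manure_ch4")
  if (is.null(manure_system_label) || !nzchar(manure_system_label)) {
    stop_validation("manure_ch4: manure_system_label is required",
                    fields = "manure_system_label")
  }
  vs * params$b0 * params$ch4_density * params$mcf
}

#' Manure nitrous oxide and ammonia
#'
#' Direct N2O: `Nex x EF3 x 44/28`. Indirect N2O:
#' `(Nex x FracGas x EF4 + Nex x FracLeach x EF5) x 44/28`. Ammonia:
#' `Nex x FracGas x 17/14`, unless a per-head factor overrides.
#'
#' @param n_excreted Nitrogen excreted, kg N/cow/yr; must be >= 0.
#' @param params An [emission_params()].
#' @return List with `n2o_direct`, `n2o_indirect`, `nh3` (kg/cow/yr) and
#'   `n_leached` (kg N/cow/yr, for eutrophication characterization).
#' @export
manure_n2o <- function(n_excreted, params = emission_params()) {
  if (!is_num1(n_excreted) || n_excreted < 0) {
    stop_validation("manure_n2o: n_excreted must be >= 0 (intake minus retention)",
                    fields = "n_excreted")
  }
  n2o_n_direct <- n_excreted * params$ef3
  n2o_n_indirect <- n_excreted * params$frac_gas * params$ef4 +
    n_excreted * params$frac_leach * params$ef5
  nh3 <- if (!is.null(params$nh3_ef)) {
    params$nh3_ef
  } else {
    n_excreted * params$frac_gas * 17 / 14
  }
  list(
    n2o_direct = n2o_n_direct * 44 / 28,
    n2o_indirect = n2o_n_indirect * 44 / 28,
    nh3 = nh3,
    n_leached = n_excreted * params$frac_leach
  )
}

#' Direct on-farm CO2 from utility use
#'
#' Sums quantity x factor over the reference system's utility items using the
#' climate-change column of the emission-factor table. Utility keys mapped to
#' their own report rows (`energy`, `water`) are excluded here; everything
#' else (fuel, bedding) is direct on-farm CO2.
#'
#' @param ref A [reference_system()].
#' @param ef An [ef_table()].
#' @param exclude Utility names reported under their own source rows.
#' @param item_map Named character vector mapping utility names to EF-table
#'   item keys (identity by default).
#' @return Direct CO2, kg/cow/yr.
#' @export
utility_co2 <- function(ref, ef, exclude = c("energy", "water"),
                        item_map = NULL) {
  stopifnot(inherits(ref, "reference_system"))
  items <- ref$utilities[setdiff(names(ref$utilities), exclude)]
  items <- items[items > 0]
  if (length(items) == 0L) return(0)
  if (is.null(item_map)) item_map <- default_item_map(names(ref$utilities))
  sum(vapply(names(items), function(k) {
    items[[k]] * ef_factor(ef, item_map[[k]], "CC")
  }, numeric(1)))
}

#' On-farm emission flows per cow-year
#'
#' Runs the Tier-2 chain on an annual profile: enteric CH4 (measured override
#' within the trial window when available), manure CH4 from volatile solids,
#' direct and indirect N2O, NH3, leached N, direct utility CO2, and per-head
#' NMVOC/PM. CH4 and N2O flows are multiplied by the params' whole-system
#' scale factors.
#'
#' @param profile An [annual_profile()][annualize()].
#' @param ref A [reference_system()].
#' @param params An [emission_params()].
#' @param ef An [ef_table()] (for direct utility CO2).
#' @param item_map Optional utility-name to item-key map (see [farm_system()]).
#' @return An object of class `emission_flows`: named list of kg/cow/yr masses.
#' @export
emission_flows <- function(profile, ref, params = emission_params(), ef = NULL,
                           item_map = NULL) {
  stopifnot(inherits(profile, "annual_profile"))
  ge_window <- profile$ge_annual * profile$fi_trial / profile$fi_annual
  ch4_ent <- enteric_ch4(
    profile$ge_annual, params,
    measured_daily = profile$measured_ch4_daily,
    measured_days = profile$duration_days,
    ge_measured_window = ge_window
  )
  vs <- volatile_solids(profile$ge_annual, params)
  ch4_man <- manure_ch4(vs, params, ref$manure_system_label)

  n_intake <- if (!is.null(params$n_intake_annual)) {
    params$n_intake_annual
  } else {
    profile$fi_annual * params$cp_fraction / 6.25
  }
  nex <- n_intake * (1 - params$n_retention_fraction)
  n2o <- manure_n2o(nex, params)

  co2 <- if (is.null(ef)) 0 else utility_co2(ref, ef, item_map = item_map)

  structure(list(
    ch4_enteric = as.numeric(ch4_ent) * params$ch4_scale,
    ch4_manure = ch4_man * params$ch4_scale,
    n2o_direct = n2o$n2o_direct * params$n2o_scale,
    n2o_indirect = n2o$n2o_indirect * params$n2o_scale,
    nh3 = n2o$nh3 * params$n2o_scale,
    n_leached = n2o$n_leached * params$n2o_scale,
    co2_direct = co2,
    nmvoc = params$nmvoc_ef,
    pm10 = params$pm10_ef,
    pm25 = params$pm25_ef,
    ch4_provenance = attr(ch4_ent, "provenance")
  ), class = "emission_flows")
}
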