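#' Trial-window zootechnical record
#'
#' One group's measurements over a defined lactation window: daily milk yield,
#' milk composition, dry-matter intake, additive dose, and (optionally) a
#' measured daily enteric methane emission. The window is expressed in 1-based
#' inclusive days in milk, so `duration_days == end_day - start_day + 1`.
#'
#' @param group_label `"control"` or `"treatment"`.
#' @param start_day,end_day Lactation window, 1-based inclusive days in milk.
#' @param milk_yield_daily Milk yield during the trial, kg/cow/d.
#' @param fat_pct,protein_pct Milk fat and protein content, % m/m, in (0, 10).
#' @param dmi_daily Dry-matter intake during the trial, kg DM/cow/d.
#' @param additive_dose Additive dose, g/cow/d (0 for control groups).
#' @param n_cows Number of cows in the group.
#' @param measured_ch4_daily Optional measured enteric methane, kg/cow/d. When
#'   present it overrides the Tier-2 model within the trial window.
#' @param gaei Optional gross annual energy intake, MJ/cow/yr, as reported by
#'   the trial; when absent it is derived from annual intake and the diet's
#'   energy density.
#' @param se Optional named list of standard errors for uncertain zootechnical
#'   inputs (`milk_yield_daily`, `dmi_daily`, `fat_pct`, `protein_pct`), used
#'   by the Monte Carlo stage.
#' @param reported_annual_milk Optional annual milk total (kg/cow/yr) as
#'   reported by the source inventory, carried as metadata alongside the value
#'   the pipeline recomputes.
#'
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(group_label, start_day, end_day, milk_yield_daily,
                         fat_pct, protein_pct, dmi_daily, additive_dose = 0,
                         n_cows = 1L, measured_ch4_daily = NULL, gaei = NULL,
                         se = NULL, reported_annual_milk = NULL) {
  check_fields(list(
    group_label = is.character(group_label) && length(group_label) == 1L &&
      group_label %in% c("control", "treatment"),
    start_day = is_num1(start_day) && start_day >= 1 && start_day == round(start_day),
    end_day = is_num1(end_day) && end_day >= start_day && end_day == round(end_day),
    milk_yield_daily = is_pos1(milk_yield_daily),
    fat_pct = is_num1(fat_pct) && fat_pct > 0 && fat_pct < 10,
    protein_pct = is_num1(protein_pct) && protein_pct > 0 && protein_pct < 10,
    dmi_daily = is_pos1(dmi_daily),
    additive_dose = is_nonneg1(additive_dose),
    n_cows = is_num1(n_cows) && n_cows >= 1 && n_cows == round(n_cows),
    measured_ch4_daily = is.null(measured_ch4_daily) || is_pos1(measured_ch4_daily),
    gaei = is.null(gaei) || is_pos1(gaei),
    reported_annual_milk = is.null(reported_annual_milk) || is_pos1(reported_annual_milk)
  ), "trial_record")
  structure(list(
    group_label = group_label,
    start_day = as.integer(start_day),
    end_day = as.integer(end_day),
    duration_days = as.integer(end_day - start_day + 1),
    milk_yield_daily = milk_yield_daily,
    fat_pct = fat_pct,
    protein_pct = protein_pct,
    dmi_daily = dmi_daily,
    additive_dose = additive_dose,
    n_cows = as.integer(n_cows),
    measured_ch4_daily = measured_ch4_daily,
    gaei = gaei,
    se = se,
    reported_annual_milk = reported_annual_milk
  ), class = "trial_record")
}

#' Country reference dairy system
#'
#' The average-farm backdrop a trial is embedded in: annual reference milk
#' yield, lactation and dry-period lengths, milk yield and feed intake outside
#' the trial window, herd coproduct mass for allocation, and per-cow-year
#' utility quantities keyed into the emission-factor table.
#'
#' @param country_label Free-text label.
#' @param annual_reference_milk Annual milk yield of the reference system,
#'   kg/cow/yr.
#' @param lactation_days,dry_days Lactation and dry-period lengths, d
#'   (defaults 305 and 60; their sum may not exceed 366).
#' @param dry_period_fi Feed intake over the dry period, kg DM/cow.
#' @param my_outside_trial Milk yield over the lactation days outside the trial
#'   window, kg/cow; identical for control and treatment by assumption. When
#'   `NULL` it is prorated from `annual_reference_milk` over the remaining
#'   lactation days.
#' @param fi_outside_override Optional outside-trial feed intake, kg DM/cow,
#'   taken from the source inventory instead of the proportional extrapolation.
#' @param herd_coproduct_liveweight Live weight of all animals sold per
#'   cow-year, kg, used by the biophysical allocation.
#' @param utilities Named numeric vector of per-cow-year utility quantities
#'   (e.g. `energy`, `water`, `bedding`, `fuel`), each keyed into the
#'   emission-factor table.
#' @param manure_system_label Manure management system label (required by the
#'   manure methane model).
#'
#' @return An object of class `reference_system`.
#' @export
reference_system <- function(country_label, annual_reference_milk,
                             lactation_days = 305, dry_days = 60,
                             dry_period_fi = 600, my_outside_trial = NULL,
                             fi_outside_override = NULL,
                             herd_coproduct_liveweight = 0,
                             utilities = c(energy = 0, water = 0, bedding = 0),
                             manure_system_label = "liquid_slurry") {
  check_fields(list(
    country_label = is.character(country_label) && length(country_label) == 1L,
    annual_reference_milk = is_nonneg1(annual_reference_milk),
    lactation_days = is_pos1(lactation_days),
    dry_days = is_nonneg1(dry_days),
    period_total = is_num1(lactation_days) && is_num1(dry_days) &&
      lactation_days + dry_days <= 366,
    dry_period_fi = is_nonneg1(dry_period_fi),
    my_outside_trial = is.null(my_outside_trial) || is_nonneg1(my_outside_trial),
    fi_outside_override = is.null(fi_outside_override) || is_nonneg1(fi_outside_override),
    herd_coproduct_liveweight = is_nonneg1(herd_coproduct_liveweight),
    utilities = is.numeric(utilities) && all(utilities >= 0) &&
      (length(utilities) == 0 || !is.null(names(utilities))),
    manure_system_label = is.character(manure_system_label) &&
      length(manure_system_label) == 1L && nzchar(manure_system_label)
  ), "reference_system")
  structure(list(
    country_label = country_label,
    annual_reference_milk = annual_reference_milk,
    lactation_days = lactation_days,
    dry_days = dry_days,
    dry_period_fi = dry_period_fi,
    my_outside_trial = my_outside_trial,
    fi_outside_override = fi_outside_override,
    herd_coproduct_liveweight = herd_coproduct_liveweight,
    utilities = utilities,
    manure_system_label = manure_system_label
  ), class = "reference_system")
}

#' Diet composition
#'
#' An optional ingredient-level description of the ration. The pipeline can run
#' without it (intake and gross energy supplied directly); when present it
#' provides the compound/roughage split, a gross-energy density, and a
#' crude-protein route to nitrogen intake.
#'
#' @param ingredient_key Character vector of emission-factor table item keys.
#' @param share Share of total dry matter per ingredient; must sum to 1.
#' @param dm_fraction Dry-matter fraction of each ingredient as fed.
#' @param ge_density Gross energy density, MJ/kg DM.
#' @param cp_fraction Crude-protein fraction of DM.
#' @param digestibility Digestible fraction of gross energy.
#' @param is_roughage Logical; `TRUE` rows report under "Roughages", others
#'   under "Feed compounds".
#'
#' @return An object of class `diet` (a data frame).
#' @export
diet <- function(ingredient_key, share, dm_fraction = 1, ge_density = 18.45,
                 cp_fraction = 0.16, digestibility = 0.7,
                 is_roughage = FALSE) {
  d <- data.frame(
    ingredient_key = as.character(ingredient_key),
    share = share,
    dm_fraction = dm_fraction,
    ge_density = ge_density,
    cp_fraction = cp_fraction,
    digestibility = digestibility,
    is_roughage = is_roughage,
    stringsAsFactors = FALSE
  )
  check_fields(list(
    ingredient_key = all(nzchar(d$ingredient_key)) && !anyDuplicated(d$ingredient_key),
    share = all(is.finite(d$share)) && all(d$share >= 0) &&
      abs(sum(d$share) - 1) <= 1e-9,
    dm_fraction = all(d$dm_fraction >= 0 & d$dm_fraction <= 1),
    ge_density = all(d$ge_density > 0),
    cp_fraction = all(d$cp_fraction >= 0 & d$cp_fraction <= 1),
    digestibility = all(d$digestibility >= 0 & d$digestibility <= 1)
  ), "diet")
  class(d) <- c("diet", "data.frame")
  d
}

#' Farm system
#'
#' Bundles one trial record with its reference system, an optional diet,
#' emission-parameter overrides, and the allocation mode into the runnable unit
#' every downstream stage consumes.
#'
#' @param trial A [trial_record()].
#' @param reference A [reference_system()].
#' @param diet Optional [diet()].
#' @param params Optional [emission_params()] overriding the defaults.
#' @param allocation `"biophysical"` or `"none"`.
#' @param compound_share Share of annual intake reported as compound feed (the
#'   remainder is roughage) when no diet is supplied.
#' @param item_map Named character vector mapping the pipeline's item roles
#'   (`compound`, `roughage`, `luc`, `additive`, and any utility names) to
#'   emission-factor table item keys, so one table can carry country-specific
#'   rows. Roles not named keep their defaults.
#' @param schema_version File-format schema version carried through
#'   serialization.
#'
#' @return An object of class `farm_system`.
#' @export
farm_system <- function(trial, reference, diet = NULL, params = NULL,
                        allocation = c("biophysical", "none"),
                        compound_share = 0.4, item_map = NULL,
                        schema_version = 1L) {
  allocation <- match.arg(allocation)
  map <- default_item_map(names(reference$utilities))
  if (!is.null(item_map)) {
    stopifnot(is.character(item_map), !is.null(names(item_map)))
    map[names(item_map)] <- item_map
  }
  check_fields(list(
    trial = inherits(trial, "trial_record"),
    reference = inherits(reference, "reference_system"),
    diet = is.null(diet) || inherits(diet, "diet"),
    params = is.null(params) || inherits(params, "emission_params"),
    compound_share = is_frac1(compound_share),
    window_fits = trial$end_day <= reference$lactation_days
  ), "farm_system")
  structure(list(
    trial = trial,
    reference = reference,
    diet = diet,
    params = if (is.null(params)) emission_params() else params,
    allocation = allocation,
    compound_share = compound_share,
    item_map = map,
    schema_version = as.integer(schema_version)
  ), class = "farm_system")
}

# Identity role -> item-key map covering the feed roles and any utility names.
default_item_map <- function(utility_names = character()) {
  roles <- unique(c("compound", "roughage", "luc", "additive", utility_names))
  keys <- c(compound = "compound_feed", roughage = "roughage",
            luc = "luc", additive = "additive")
  out <- stats::setNames(roles, roles)
  out[names(keys)[names(keys) %in% roles]] <-
    keys[names(keys) %in% roles]
  out
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> %s: days %d-%d (%d d), MY %.1f kg/d, fat %.2f%%, protein %.2f%%, DMI %.1f kg DM/d, dose %g g/d, n=%d\n",
    x$group_label, x$start_day, x$end_day, x$duration_days,
    x$milk_yield_daily, x$fat_pct, x$protein_pct, x$dmi_daily,
    x$additive_dose, x$n_cows
  ))
  invisible(x)
}

#' @export
print.farm_system <- function(x, ...) {
  cat(sprintf("<farm_system> %s / %s, allocation: %s\n",
              x$reference$country_label, x$trial$group_label, x$allocation))
  print(x$trial)
  invisible(x)
}

#' Resolve every item key a farm system references against an EF table
#'
#' @param system A [farm_system()].
#' @param ef An [ef_table()].
#' @return Invisibly `TRUE`; signals a resolution error naming any missing key.
#' @export
resolve_items <- function(system, ef) {
  map <- system$item_map
  needed <- c(
    if (!is.null(system$diet)) system$diet$ingredient_key
    else unname(map[c("compound", "roughage")]),
    unname(map[c("additive", "luc")]),
    unname(map[names(system$reference$utilities)[system$reference$utilities > 0]])
  )
  missing <- setdiff(unique(needed), unique(ef$item_key))
  if (length(missing)) {
    stop_resolution(
      sprintf("unresolved item key(s) in emission-factor table: %s",
              paste(missing, collapse = ", ")),
      keys = missing
    )
  }
  invisible(TRUE)
}
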