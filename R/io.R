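#' Read and write farm-system files
#'
#' Farm systems serialize to a structured key/value text format (YAML) with an
#' explicit `schema_version`, so inputs are human-diffable and versioned.
#' Reading validates eagerly through the type constructors: any invariant
#' violation raises a validation error listing the offending field paths.
#' Unknown emission-factor item keys are not checked here — resolution happens
#' when the system is paired with a table (see [resolve_items()]).
#'
#' @param path File path.
#' @return `read_farm_system` returns a [farm_system()];
#'   `write_farm_system` returns `path` invisibly.
#' @export
read_farm_system <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("farm-system file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version)) {
    stop_validation("farm-system file lacks schema_version", fields = "schema_version")
  }
  tr <- raw$trial
  trial <- trial_record(
    group_label = tr$group_label,
    start_day = tr$start_day, end_day = tr$end_day,
    milk_yield_daily = tr$milk_yield_daily,
    fat_pct = tr$fat_pct, protein_pct = tr$protein_pct,
    dmi_daily = tr$dmi_daily,
    additive_dose = tr$additive_dose %||% 0,
    n_cows = tr$n_cows %||% 1L,
    measured_ch4_daily = tr$measured_ch4_daily,
    gaei = tr$gaei,
    se = tr$se,
    reported_annual_milk = tr$reported_annual_milk
  )
  rf <- raw$reference
  utilities <- if (is.null(rf$utilities)) {
    c(energy = 0, water = 0, bedding = 0)
  } else {
    unlist(rf$utilities)
  }
  reference <- reference_system(
    country_label = rf$country_label,
    annual_reference_milk = rf$annual_reference_milk,
    lactation_days = rf$lactation_days %||% 305,
    dry_days = rf$dry_days %||% 60,
    dry_period_fi = rf$dry_period_fi %||% 600,
    my_outside_trial = rf$my_outside_trial,
    fi_outside_override = rf$fi_outside_override,
    herd_coproduct_liveweight = rf$herd_coproduct_liveweight %||% 0,
    utilities = utilities,
    manure_system_label = rf$manure_system_label %||% "liquid_slurry"
  )
  d <- if (!is.null(raw$diet)) {
    diet(
      ingredient_key = vapply(raw$diet, `[[`, character(1), "ingredient_key"),
      share = vapply(raw$diet, `[[`, numeric(1), "share"),
      dm_fraction = vapply(raw$diet, `[[`, numeric(1), "dm_fraction"),
      ge_density = vapply(raw$diet, `[[`, numeric(1), "ge_density"),
      cp_fraction = vapply(raw$diet, `[[`, numeric(1), "cp_fraction"),
      digestibility = vapply(raw$diet, `[[`, numeric(1), "digestibility"),
      is_roughage = vapply(raw$diet, `[[`, logical(1), "is_roughage")
    )
  }
  params <- if (!is.null(raw$params)) {
    do.call(emission_params, raw$params)
  }
  farm_system(
    trial = trial, reference = reference, diet = d, params = params,
    allocation = raw$allocation %||% "biophysical",
    compound_share = raw$compound_share %||% 0.4,
    item_map = if (!is.null(raw$item_map)) unlist(raw$item_map),
    schema_version = raw$schema_version
  )
}

#' @rdname read_farm_system
#' @param system A [farm_system()] to serialize.
#' @export
write_farm_system <- function(system, path) {
  stopifnot(inherits(system, "farm_system"))
  tr <- system$trial
  rf <- system$reference
  payload <- list(
    schema_version = system$schema_version,
    allocation = system$allocation,
    compound_share = system$compound_share,
    item_map = as.list(system$item_map),
    trial = drop_null(list(
      group_label = tr$group_label,
      start_day = tr$start_day, end_day = tr$end_day,
      milk_yield_daily = tr$milk_yield_daily,
      fat_pct = tr$fat_pct, protein_pct = tr$protein_pct,
      dmi_daily = tr$dmi_daily, additive_dose = tr$additive_dose,
      n_cows = tr$n_cows, measured_ch4_daily = tr$measured_ch4_daily,
      gaei = tr$gaei, se = tr$se,
      reported_annual_milk = tr$reported_annual_milk
    )),
    reference = drop_null(list(
      country_label = rf$country_label,
      annual_reference_milk = rf$annual_reference_milk,
      lactation_days = rf$lactation_days, dry_days = rf$dry_days,
      dry_period_fi = rf$dry_period_fi,
      my_outside_trial = rf$my_outside_trial,
      fi_outside_override = rf$fi_outside_override,
      herd_coproduct_liveweight = rf$herd_coproduct_liveweight,
      utilities = as.list(rf$utilities),
      manure_system_label = rf$manure_system_label
    )),
    params = non_default_params(system$params)
  )
  if (!is.null(system$diet)) {
    payload$diet <- lapply(seq_len(nrow(system$diet)), function(i) {
      as.list(system$diet[i, , drop = FALSE])
    })
  }
  yaml::write_yaml(drop_null(payload), path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

# Serialize only emission parameters that differ from the defaults, so files
# stay diffable against the canonical parameter set.
non_default_params <- function(params) {
  def <- unclass(emission_params())
  cur <- unclass(params)
  keep <- names(cur)[vapply(names(cur), function(k) {
    !identical(cur[[k]], def[[k]])
  }, logical(1))]
  if (length(keep) == 0L) NULL else cur[keep]
}

#' Write a comparison report
#'
#' Emits two files: `<path>.json`, a machine-readable structured report that
#' [read_report()] parses back, and `<path>.txt`, a plain-text
#' climate-change contribution table whose rows follow the conventional
#' source layout (Feed compounds, Roughages, On farm CO2, On-farm N2O,
#' On farm CH4, Energy at Farm, Water at Farm, Additive, Land use change).
#'
#' @param report A [compare()] result.
#' @param path Output path stem (extensions are appended).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "comparison_report") || is.null(report$table) ||
      nrow(report$table) == 0) {
    stop_validation("write_report: empty or invalid comparison report")
  }
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")

  payload <- list(
    table = report$table,
    breakdown_cc = list(
      source = rownames(report$breakdown_cc),
      control = unname(report$breakdown_cc[, "control"]),
      treatment = unname(report$breakdown_cc[, "treatment"])
    ),
    af = as.list(report$af),
    fpcm_annual = as.list(report$fpcm_annual),
    window_only = isTRUE(report$window_only)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  labels <- source_labels()
  bd <- report$breakdown_cc
  lines <- c(
    "Contribution to climate change (kg CO2 eq per kg FPCM)",
    sprintf("%-16s %10s %10s", "Source", "Control", "Treatment"),
    sprintf("%-16s %10.4f %10.4f", "Total",
            sum(bd[, "control"]), sum(bd[, "treatment"])),
    vapply(rownames(bd), function(s) {
      sprintf("%-16s %10.4f %10.4f", labels[[s]], bd[s, "control"], bd[s, "treatment"])
    }, character(1))
  )
  writeLines(lines, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  bd <- cbind(control = raw$breakdown_cc$control,
              treatment = raw$breakdown_cc$treatment)
  rownames(bd) <- raw$breakdown_cc$source
  structure(list(
    table = as.data.frame(raw$table, stringsAsFactors = FALSE),
    breakdown_cc = bd,
    af = unlist(raw$af),
    fpcm_annual = unlist(raw$fpcm_annual),
    window_only = if (isTRUE(raw$window_only)) TRUE else NULL,
    uncertainty = NULL
  ), class = "comparison_report")
}
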