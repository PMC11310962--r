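#' Compare a control and a treatment impact result
#'
#' Per-category relative difference with the control as denominator,
#' `diff_pct = (treatment - control) / control x 100`, plus the additive's
#' own share of the treatment total. Negative `diff_pct` is a reduction.
#'
#' @param control,treatment [impact_result()] objects over the same category
#'   set.
#' @return An object of class `comparison_report`: a list with `table` (data
#'   frame: category, unit, control, treatment, diff_pct,
#'   additive_share_pct), the two CC source breakdowns, and metadata.
#' @export
compare <- function(control, treatment) {
  stopifnot(inherits(control, "impact_result"), inherits(treatment, "impact_result"))
  if (!identical(names(control$total), names(treatment$total))) {
    stop_validation("compare: impact-category sets differ", fields = "total")
  }
  cats <- impact_categories()
  c_val <- control$total[cats$key]
  t_val <- treatment$total[cats$key]
  diff_pct <- ifelse(c_val == 0, ifelse(t_val == 0, 0, NA_real_),
                     (t_val - c_val) / c_val * 100)
  add_share <- ifelse(t_val == 0, 0,
                      100 * treatment$breakdown["additive", cats$key] / t_val)
  structure(list(
    table = data.frame(
      category = cats$key,
      unit = cats$unit,
      control = unname(c_val * cats$display_scale),
      treatment = unname(t_val * cats$display_scale),
      diff_pct = unname(diff_pct),
      additive_share_pct = unname(add_share),
      stringsAsFactors = FALSE
    ),
    breakdown_cc = cbind(control = control$breakdown[, "CC"],
                         treatment = treatment$breakdown[, "CC"]),
    af = c(control = control$af, treatment = treatment$af),
    fpcm_annual = c(control = control$fpcm_annual,
                    treatment = treatment$fpcm_annual),
    window_only = NULL,
    uncertainty = NULL
  ), class = "comparison_report")
}

#' Average comparison reports across trials
#'
#' Table-style aggregation over several paired trials: unweighted means of the
#' per-trial control values, treatment values, and relative differences.
#'
#' @param reports List of [compare()] results.
#' @return Data frame: category, unit, control_mean, treatment_mean,
#'   diff_pct_mean.
#' @export
aggregate_comparisons <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "comparison_report")))
  tabs <- lapply(reports, `[[`, "table")
  base <- tabs[[1]][c("category", "unit")]
  pick <- function(col) rowMeans(sapply(tabs, `[[`, col))
  data.frame(
    base,
    control_mean = pick("control"),
    treatment_mean = pick("treatment"),
    diff_pct_mean = pick("diff_pct"),
    stringsAsFactors = FALSE
  )
}

#' Window-only comparison of a supplementation trial
#'
#' Same arithmetic as [compare()] with impacts and the FPCM functional unit
#' restricted to the supplementation window. Because the outside-window
#' period is equalized across groups by construction, the annual difference
#' is a diluted version of the window difference.
#'
#' @param control,treatment [farm_system()] objects with matching trial
#'   windows.
#' @param ef An [ef_table()].
#' @param cf A [characterization_factors()].
#' @return A `comparison_report` with `window_only = TRUE`.
#' @export
supplementation_window_compare <- function(control, treatment, ef,
                                           cf = characterization_factors()) {
  if (control$trial$start_day != treatment$trial$start_day ||
      control$trial$end_day != treatment$trial$end_day) {
    stop_validation("supplementation_window_compare: trial windows differ",
                    fields = c("start_day", "end_day"))
  }
  res <- assess_pair(control, treatment, ef, cf, window_only = TRUE)
  out <- compare(res$control, res$treatment)
  out$window_only <- TRUE
  out
}

#' Paired Monte Carlo uncertainty of a comparison
#'
#' Propagates input uncertainty into the per-category relative difference by
#' resampling: emission factors draw lognormal multipliers from their
#' geometric standard deviations, and trial zootechnical inputs draw normal
#' values from their standard errors. In the default paired mode the same
#' emission-factor draw is applied to both systems in each iteration
#' (common random numbers), so shared-chain uncertainty cancels out of the
#' difference instead of swamping it; an unpaired mode draws independently
#' for contrast.
#'
#' With every `gsd = 1` and no standard errors the distributions are
#' degenerate and every iteration reproduces the point estimate. Results are
#' reproducible from `seed`.
#'
#' @param control,treatment [farm_system()] objects.
#' @param ef An [ef_table()] carrying `gsd` uncertainty.
#' @param cf A [characterization_factors()].
#' @param n_iter Number of iterations (>= 1), conventionally 1000.
#' @param seed Integer seed; required.
#' @param paired Use common random numbers across the two systems.
#' @param window_only Propagate through the window-only accounting instead.
#' @return An object of class `mc_summary`: list with `summary` (data frame:
#'   category, point, median, q025, q975 of diff_pct), the draws matrix, and
#'   the call settings.
#' @export
monte_carlo <- function(control, treatment, ef,
                        cf = characterization_factors(),
                        n_iter = 1000, seed, paired = TRUE,
                        window_only = FALSE) {
  if (!is_num1(n_iter) || n_iter < 1) {
    stop_validation("monte_carlo: n_iter must be >= 1", fields = "n_iter")
  }
  stopifnot(is_num1(seed))
  cats <- category_keys()

  point_pair <- assess_pair(control, treatment, ef, cf, window_only = window_only)
  point <- compare(point_pair$control, point_pair$treatment)$table$diff_pct

  draw_ef <- function() {
    mult <- exp(stats::rnorm(nrow(ef)) * log(ef$gsd))
    ef2 <- ef
    ef2$value <- ef$value * mult
    ef2
  }
  draws <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, nrow = n_iter, ncol = length(cats),
                  dimnames = list(NULL, cats))
    for (i in seq_len(n_iter)) {
      ef_c <- draw_ef()
      ef_t <- if (paired) ef_c else draw_ef()
      ctl <- perturb_system(control)
      trt <- perturb_system(treatment)
      rc <- assess_system(ctl, ef_c, cf, control_trial = ctl$trial,
                          window_only = window_only)
      rt <- assess_system(trt, ef_t, cf, control_trial = ctl$trial,
                          window_only = window_only)
      out[i, ] <- compare(rc, rt)$table$diff_pct
    }
    out
  })
  qs <- apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE)
  structure(list(
    summary = data.frame(
      category = cats,
      point = point,
      median = qs[1, ],
      q025 = qs[2, ],
      q975 = qs[3, ],
      stringsAsFactors = FALSE
    ),
    draws = draws,
    n_iter = n_iter, seed = as.integer(seed), paired = paired,
    window_only = window_only
  ), class = "mc_summary")
}

# Redraw a system's uncertain zootechnical inputs from their standard errors.
perturb_system <- function(system) {
  se <- system$trial$se
  if (is.null(se) || length(se) == 0) return(system)
  tr <- system$trial
  for (field in names(se)) {
    if (!field %in% c("milk_yield_daily", "dmi_daily", "fat_pct", "protein_pct")) {
      stop_validation(sprintf("unknown uncertain trial field: %s", field),
                      fields = field)
    }
    val <- stats::rnorm(1, mean = tr[[field]], sd = se[[field]])
    tr[[field]] <- max(val, 0.05 * tr[[field]])  # guard against negative draws
  }
  system$trial <- trial_record(
    tr$group_label, tr$start_day, tr$end_day, tr$milk_yield_daily,
    tr$fat_pct, tr$protein_pct, tr$dmi_daily, tr$additive_dose, tr$n_cows,
    tr$measured_ch4_daily, tr$gaei, tr$se, tr$reported_annual_milk
  )
  system
}

#' One-at-a-time sensitivity of a paired comparison
#'
#' Central-difference elasticities of the control climate-change total and of
#' the paired climate-change difference with respect to a relative
#' perturbation of each listed parameter. Parameters may live in the trial
#' records (`milk_yield_daily`, `dmi_daily`, `fat_pct`, `protein_pct`,
#' `additive_dose`), the emission parameters (`ym`, `b0`, `mcf`, `ef3`, ...),
#' or the characterization factors (`gwp_ch4`, `gwp_n2o`, ...); trial and
#' emission parameters are perturbed jointly in both systems.
#'
#' For a linear driver the elasticity of the total equals that driver's
#' contribution share — e.g. the Ym elasticity equals the modeled enteric
#' methane share of the climate-change total.
#'
#' @param control,treatment [farm_system()] objects.
#' @param ef An [ef_table()].
#' @param cf A [characterization_factors()].
#' @param parameters Character vector of parameter names.
#' @param perturbation Relative perturbation (e.g. 0.05 for +/-5%); 0 returns
#'   zero elasticities.
#' @return Data frame ranked by absolute elasticity: parameter,
#'   elasticity_cc_total (d ln total / d ln parameter), sensitivity_diff_pct
#'   (d diff_pct / d ln parameter, percentage points).
#' @export
sensitivity_oat <- function(control, treatment, ef,
                            cf = characterization_factors(),
                            parameters = c("milk_yield_daily", "dmi_daily", "ym"),
                            perturbation = 0.05) {
  stopifnot(is_num1(perturbation), perturbation >= 0, perturbation < 1)
  eval_cc <- function(ctl, trt, cfx) {
    res <- assess_pair(ctl, trt, ef, cfx)
    cmp <- compare(res$control, res$treatment)
    c(total = unname(res$control$total[["CC"]]),
      diff = cmp$table$diff_pct[cmp$table$category == "CC"])
  }
  base <- eval_cc(control, treatment, cf)
  rows <- lapply(parameters, function(p) {
    if (perturbation == 0) {
      return(data.frame(parameter = p, elasticity_cc_total = 0,
                        sensitivity_diff_pct = 0, stringsAsFactors = FALSE))
    }
    up <- apply_parameter(control, treatment, cf, p, 1 + perturbation)
    dn <- apply_parameter(control, treatment, cf, p, 1 - perturbation)
    f_up <- eval_cc(up$control, up$treatment, up$cf)
    f_dn <- eval_cc(dn$control, dn$treatment, dn$cf)
    data.frame(
      parameter = p,
      elasticity_cc_total =
        (f_up[["total"]] - f_dn[["total"]]) / (2 * perturbation * base[["total"]]),
      sensitivity_diff_pct =
        (f_up[["diff"]] - f_dn[["diff"]]) / (2 * perturbation),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$elasticity_cc_total)), , drop = FALSE]
}

# Multiply one named parameter by `mult` wherever it lives.
apply_parameter <- function(control, treatment, cf, param, mult) {
  trial_fields <- c("milk_yield_daily", "dmi_daily", "fat_pct", "protein_pct",
                    "additive_dose")
  scale_trial <- function(system) {
    tr <- system$trial
    tr[[param]] <- tr[[param]] * mult
    system$trial <- trial_record(
      tr$group_label, tr$start_day, tr$end_day, tr$milk_yield_daily,
      tr$fat_pct, tr$protein_pct, tr$dmi_daily, tr$additive_dose, tr$n_cows,
      tr$measured_ch4_daily, tr$gaei, tr$se, tr$reported_annual_milk
    )
    system
  }
  scale_params <- function(system) {
    p <- unclass(system$params)
    p[[param]] <- p[[param]] * mult
    system$params <- do.call(emission_params,
                             p[setdiff(names(p), character())])
    system
  }
  if (param %in% trial_fields) {
    list(control = scale_trial(control), treatment = scale_trial(treatment), cf = cf)
  } else if (param %in% names(emission_params())) {
    list(control = scale_params(control), treatment = scale_params(treatment), cf = cf)
  } else if (param %in% names(cf)) {
    cf2 <- unclass(cf)
    cf2[[param]] <- cf2[[param]] * mult
    list(control = control, treatment = treatment,
         cf = do.call(characterization_factors, cf2))
  } else {
    stop_validation(sprintf("unknown sensitivity parameter: %s", param),
                    fields = param)
  }
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>",
      if (isTRUE(x$window_only)) "(supplementation window only)" else "(annual)",
      "\n")
  tab <- x$table
  tab$control <- signif(tab$control, 4)
  tab$treatment <- signif(tab$treatment, 4)
  tab$diff_pct <- round(tab$diff_pct, 2)
  tab$additive_share_pct <- signif(tab$additive_share_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
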