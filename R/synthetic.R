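#' Synthetic scenario configuration
#'
#' Describes a family of internally consistent control/treatment trial pairs:
#' base zootechnical ranges for the control groups, a multiplicative treatment
#' effect model inside the supplementation window (means and SDs of the
#' multipliers on milk yield, intake, fat and protein), emission-factor table
#' size and uncertainty range, and reference-system ranges. The effect-model
#' defaults span the spread seen across published additive trials: a few
#' percent more milk at equal-to-slightly-changed intake.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_trials Number of control/treatment pairs.
#' @param my_effect_mean,my_effect_sd Treatment multiplier on milk yield.
#' @param dmi_effect_mean,dmi_effect_sd Treatment multiplier on intake.
#' @param fat_effect_mean,fat_effect_sd Treatment multiplier on fat %.
#' @param protein_effect_mean,protein_effect_sd Multiplier on protein %.
#' @param my_range Control daily milk yield range, kg/d.
#' @param dmi_range Control daily intake range, kg DM/d.
#' @param fat_range,protein_range Control composition ranges, %.
#' @param dose_range Additive dose range, g/cow/d.
#' @param duration_range Supplementation duration range, d.
#' @param ref_milk_range Reference-system annual milk range, kg/cow/yr.
#' @param mmeat_range Coproduct live-weight range, kg/cow/yr.
#' @param n_ef_items Number of generic feed items in the generated EF table.
#' @param gsd_range Lognormal gsd range for generated factors.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_trials = 3L,
                               my_effect_mean = 1.06, my_effect_sd = 0.03,
                               dmi_effect_mean = 1.00, dmi_effect_sd = 0.04,
                               fat_effect_mean = 1.00, fat_effect_sd = 0.01,
                               protein_effect_mean = 1.00, protein_effect_sd = 0.005,
                               my_range = c(28, 48), dmi_range = c(19, 25),
                               fat_range = c(3.6, 4.4),
                               protein_range = c(3.0, 3.4),
                               dose_range = c(5, 10),
                               duration_range = c(90, 120),
                               ref_milk_range = c(7000, 12500),
                               mmeat_range = c(150, 300),
                               n_ef_items = 8L, gsd_range = c(1.05, 1.3)) {
  rng_ok <- function(r) is.numeric(r) && length(r) == 2 && all(is.finite(r)) &&
    r[1] <= r[2] && r[1] >= 0
  check_fields(list(
    seed = is_num1(seed),
    n_trials = is_num1(n_trials) && n_trials >= 1,
    my_effect_mean = is_pos1(my_effect_mean),
    dmi_effect_mean = is_pos1(dmi_effect_mean),
    fat_effect_mean = is_pos1(fat_effect_mean),
    protein_effect_mean = is_pos1(protein_effect_mean),
    my_effect_sd = is_nonneg1(my_effect_sd),
    dmi_effect_sd = is_nonneg1(dmi_effect_sd),
    fat_effect_sd = is_nonneg1(fat_effect_sd),
    protein_effect_sd = is_nonneg1(protein_effect_sd),
    my_range = rng_ok(my_range) && my_range[1] > 0,
    dmi_range = rng_ok(dmi_range) && dmi_range[1] > 0,
    fat_range = rng_ok(fat_range) && fat_range[1] > 0 && fat_range[2] < 10,
    protein_range = rng_ok(protein_range) && protein_range[1] > 0 && protein_range[2] < 10,
    dose_range = rng_ok(dose_range),
    duration_range = rng_ok(duration_range) && duration_range[1] >= 1 &&
      duration_range[2] <= 305,
    ref_milk_range = rng_ok(ref_milk_range) && ref_milk_range[1] > 0,
    mmeat_range = rng_ok(mmeat_range),
    n_ef_items = is_num1(n_ef_items) && n_ef_items >= 1,
    gsd_range = rng_ok(gsd_range) && gsd_range[1] >= 1
  ), "synthetic_scenario")
  structure(as.list(environment())[names(formals(synthetic_scenario))],
            class = "synthetic_scenario")
}

#' Generate a synthetic scenario
#'
#' Draws `n_trials` control/treatment farm-system pairs plus a matching
#' emission-factor table. Control and treatment differ only through the
#' effect-model multipliers inside the trial window; the reference system
#' (and with it all outside-window behaviour) is shared, so a null effect
#' model with zero dose yields byte-identical groups. Regeneration from the
#' same scenario is deterministic.
#'
#' @param config A [synthetic_scenario()].
#' @return List with `pairs` (each a list of `control` and `treatment`
#'   [farm_system()]s) and `ef` (an [ef_table()]).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "synthetic_scenario"))
  withr::with_seed(as.integer(config$seed), {
    ef <- synthetic_ef_table(config$n_ef_items, config$gsd_range)
    pairs <- lapply(seq_len(config$n_trials), function(i) {
      draw_pair(config, i)
    })
    names(pairs) <- sprintf("trial_%02d", seq_along(pairs))
    list(pairs = pairs, ef = ef)
  })
}

draw_unif <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

draw_mult <- function(mean, sd) {
  if (sd == 0) return(mean)
  max(stats::rnorm(1, mean, sd), 1e-3)
}

draw_pair <- function(config, idx) {
  duration <- round(draw_unif(config$duration_range))
  start <- sample.int(305 - duration + 1, 1)
  my <- draw_unif(config$my_range)
  dmi <- draw_unif(config$dmi_range)
  fat <- draw_unif(config$fat_range)
  prot <- draw_unif(config$protein_range)
  dose <- draw_unif(config$dose_range)

  ref <- reference_system(
    country_label = sprintf("synthetic_%02d", idx),
    annual_reference_milk = draw_unif(config$ref_milk_range),
    herd_coproduct_liveweight = draw_unif(config$mmeat_range),
    utilities = c(energy = stats::runif(1, 200, 800),
                  water = stats::runif(1, 10, 40),
                  fuel = stats::runif(1, 50, 200)),
    manure_system_label = "liquid_slurry"
  )
  mk <- function(label, m_my, m_dmi, m_fat, m_prot, d) {
    trial_record(
      group_label = label,
      start_day = start, end_day = start + duration - 1,
      milk_yield_daily = my * m_my, dmi_daily = dmi * m_dmi,
      fat_pct = min(fat * m_fat, 9.99), protein_pct = min(prot * m_prot, 9.99),
      additive_dose = d, n_cows = 30L
    )
  }
  control <- mk("control", 1, 1, 1, 1, 0)
  treatment <- mk(
    "treatment",
    draw_mult(config$my_effect_mean, config$my_effect_sd),
    draw_mult(config$dmi_effect_mean, config$dmi_effect_sd),
    draw_mult(config$fat_effect_mean, config$fat_effect_sd),
    draw_mult(config$protein_effect_mean, config$protein_effect_sd),
    dose
  )
  list(
    control = farm_system(control, ref),
    treatment = farm_system(treatment, ref)
  )
}

#' Generate a synthetic emission-factor table
#'
#' Covers the core item roles (compound feed, roughage, land-use-change
#' adder, additive, utilities) plus `n_items` generic feed ingredients, each
#' with a factor in every impact category and a lognormal gsd drawn from
#' `gsd_range`.
#'
#' @param n_items Number of generic feed ingredient items.
#' @param gsd_range Range for the geometric standard deviations.
#' @return An [ef_table()] with `(n_items + 8) x 8` resolvable cells.
#' @export
synthetic_ef_table <- function(n_items = 8L, gsd_range = c(1.05, 1.3)) {
  core <- c("compound_feed", "roughage", "luc", "additive",
            "energy", "water", "fuel", "bedding")
  items <- c(core, sprintf("feed_%02d", seq_len(n_items)))
  cats <- category_keys()
  # typical magnitude per category for 1 kg of a feed-chain item
  base <- c(CC = 0.6, LU = 30, WU = 0.15, RU = 2, TFWAC = 0.01,
            FEU = 0.08, MEU = 5, TEU = 0.05)
  grid <- expand.grid(item_key = items, category = cats,
                      stringsAsFactors = FALSE)
  grid$value <- base[grid$category] *
    stats::runif(nrow(grid), 0.3, 1.7) *
    ifelse(grid$item_key == "luc", 0.15, 1)
  grid$gsd <- if (gsd_range[1] == gsd_range[2]) gsd_range[1] else
    stats::runif(nrow(grid), gsd_range[1], gsd_range[2])
  ef_table(grid$item_key, grid$category, grid$value, grid$gsd)
}
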