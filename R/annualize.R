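#' Fat- and protein-corrected milk
#'
#' Normalizes a milk mass to reference fat and protein content with the linear
#' correction `FPCM = milk x (0.1226 x fat% + 0.0776 x protein% + 0.2534)`.
#' The correction is linear in milk mass, and with fat = protein = 0 the
#' factor reduces to 0.2534.
#'
#' @param milk_kg Milk mass, kg; must be >= 0.
#' @param fat_pct Fat content, % m/m, in (0, 10).
#' @param protein_pct Protein content, % m/m, in (0, 10).
#' @return FPCM mass, kg.
#' @export
#' @examples
#' fpcm(11963, 3.9, 3.25)  # ~11768 kg
fpcm <- function(milk_kg, fat_pct, protein_pct) {
  check_fields(list(
    milk_kg = is.numeric(milk_kg) && all(is.finite(milk_kg)) && all(milk_kg >= 0),
    fat_pct = is.numeric(fat_pct) && all(fat_pct >= 0) && all(fat_pct < 10),
    protein_pct = is.numeric(protein_pct) && all(protein_pct >= 0) && all(protein_pct < 10)
  ), "fpcm")
  milk_kg * (0.1226 * fat_pct + 0.0776 * protein_pct + 0.2534)
}

#' Extrapolate feed intake outside the trial window
#'
#' Outside-trial intake scales trial-window intake by the ratio of milk
#' produced outside to milk produced inside the window:
#' `FI_out = FI_trial x MY_out / MY_trial`. Under the equal-performance
#' assumption for the non-supplemented period, treatment groups receive the
#' control group's outside-trial value.
#'
#' @param fi_trial Feed intake over the trial window, kg DM/cow.
#' @param my_outside Milk yield outside the trial window, kg/cow.
#' @param my_trial Milk yield over the trial window, kg/cow; must be > 0.
#' @return Outside-trial feed intake, kg DM/cow.
#' @export
#' @examples
#' extrapolate_fi_outside(2868, 6263, 5700)  # ~3151 kg DM
extrapolate_fi_outside <- function(fi_trial, my_outside, my_trial) {
  check_fields(list(
    fi_trial = is_nonneg1(fi_trial),
    my_outside = is_nonneg1(my_outside)
  ), "extrapolate_fi_outside")
  if (!is_num1(my_trial) || my_trial <= 0) {
    stop_numerical("extrapolate_fi_outside: my_trial must be > 0 (division by trial-window milk)")
  }
  fi_trial * my_outside / my_trial
}

#' Annualize a trial record against its reference system
#'
#' Converts trial-window measurements plus the country reference system into an
#' annual per-cow profile: milk, FPCM, feed intake decomposed into trial /
#' outside-trial / dry-period parts, gross energy, trial-window feed
#' efficiency, and the annual additive mass.
#'
#' Outside-trial milk is identical across groups (reference-system assumption);
#' outside-trial intake is the control group's proportional extrapolation, or
#' the reference system's `fi_outside_override` when the inventory states it
#' directly. The additive mass contributes to the footprint but not to intake,
#' energy, or feed-efficiency denominators.
#'
#' @param trial A [trial_record()].
#' @param ref A [reference_system()].
#' @param control_trial The paired control [trial_record()]; defaults to
#'   `trial` itself (for control groups or unpaired use).
#' @param diet Optional [diet()] supplying a gross-energy density when the
#'   trial carries no GAEI.
#' @return An object of class `annual_profile`.
#' @export
annualize <- function(trial, ref, control_trial = trial, diet = NULL) {
  stopifnot(inherits(trial, "trial_record"), inherits(ref, "reference_system"))
  if (trial$end_day > ref$lactation_days) {
    stop_validation(sprintf(
      "annualize: trial window ends day %d, beyond the %g-day lactation",
      trial$end_day, ref$lactation_days
    ), fields = "end_day")
  }

  my_trial <- trial$milk_yield_daily * trial$duration_days
  my_outside <- if (!is.null(ref$my_outside_trial)) {
    ref$my_outside_trial
  } else {
    outside_days <- ref$lactation_days - trial$duration_days
    ref$annual_reference_milk * outside_days / ref$lactation_days
  }

  fi_trial <- trial$dmi_daily * trial$duration_days
  fi_outside <- if (!is.null(ref$fi_outside_override)) {
    ref$fi_outside_override
  } else {
    extrapolate_fi_outside(
      control_trial$dmi_daily * control_trial$duration_days,
      my_outside,
      control_trial$milk_yield_daily * control_trial$duration_days
    )
  }
  fi_annual <- fi_trial + fi_outside + ref$dry_period_fi

  milk_annual <- my_trial + my_outside
  fpcm_annual <- fpcm(milk_annual, trial$fat_pct, trial$protein_pct)

  ge_annual <- if (!is.null(trial$gaei)) {
    trial$gaei
  } else {
    ge_density <- if (!is.null(diet)) sum(diet$share * diet$ge_density) else 18.45
    fi_annual * ge_density
  }

  fpcm_daily <- fpcm(trial$milk_yield_daily, trial$fat_pct, trial$protein_pct)
  fe_trial <- fpcm_daily / trial$dmi_daily

  structure(list(
    milk_annual = milk_annual,
    fpcm_annual = fpcm_annual,
    my_trial = my_trial,
    my_outside = my_outside,
    fi_trial = fi_trial,
    fi_outside = fi_outside,
    fi_dry = ref$dry_period_fi,
    fi_annual = fi_annual,
    ge_annual = ge_annual,
    fe_trial = fe_trial,
    fe_annual = fpcm_annual / fi_annual,
    additive_mass_annual = trial$additive_dose * trial$duration_days / 1000,
    duration_days = trial$duration_days,
    measured_ch4_daily = trial$measured_ch4_daily
  ), class = "annual_profile")
}

#' @export
print.annual_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<annual_profile> milk %.1f kg, FPCM %.1f kg, FI %.1f kg DM ",
           "(trial %.1f + outside %.1f + dry %.1f), GE %.0f MJ, FE %.3f\n"),
    x$milk_annual, x$fpcm_annual, x$fi_annual, x$fi_trial, x$fi_outside,
    x$fi_dry, x$ge_annual, x$fe_trial
  ))
  invisible(x)
}
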