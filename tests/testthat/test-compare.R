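test_that("paired comparison arithmetic matches the published columns", {
  res <- published_impact_results(published, "uk")
  cmp <- compare(res$control, res$treatment)
  cc <- cmp$table[cmp$table$category == "CC", ]
  expect_equal(cc$control, 1.152, tolerance = 1e-9)
  expect_equal(round(-cc$diff_pct, 1), 3.1)
  # antisymmetry up to the change of denominator
  rev <- compare(res$treatment, res$control)
  rcc <- rev$table[rev$table$category == "CC", ]
  expect_equal(rcc$diff_pct, -cc$diff_pct * cc$control / cc$treatment,
               tolerance = 1e-9)
})

test_that("identical systems compare to zero difference everywhere", {
  pr <- tiny_pair(seed = 9)
  res <- assess_system(pr$control, pr$ef)
  cmp <- compare(res, res)
  expect_true(all(cmp$table$diff_pct == 0))
})

test_that("comparison requires a shared category set", {
  pr <- tiny_pair(seed = 9)
  res <- assess_system(pr$control, pr$ef)
  broken <- res
  names(broken$total)[1] <- "XX"
  expect_error(compare(res, broken), class = "dfp_validation_error")
})

test_that("trial averaging is the unweighted mean of per-trial values", {
  reports <- lapply(c("french", "uk", "german"), function(tr) {
    res <- published_impact_results(published, tr)
    compare(res$control, res$treatment)
  })
  agg <- aggregate_comparisons(reports)
  cc <- agg[agg$category == "CC", ]
  per_trial <- vapply(reports, function(r) {
    r$table$control[r$table$category == "CC"]
  }, numeric(1))
  expect_equal(cc$control_mean, mean(per_trial), tolerance = 1e-12)
})

test_that("window-only comparison of a null pair is exactly zero", {
  sc <- synthetic_scenario(seed = 21, n_trials = 1,
                           my_effect_mean = 1, my_effect_sd = 0,
                           dmi_effect_mean = 1, dmi_effect_sd = 0,
                           fat_effect_mean = 1, fat_effect_sd = 0,
                           protein_effect_mean = 1, protein_effect_sd = 0,
                           dose_range = c(0, 0))
  gen <- generate_scenario(sc)
  pair <- gen$pairs[[1]]
  win <- supplementation_window_compare(pair$control, pair$treatment, gen$ef)
  expect_true(all(win$table$diff_pct == 0))
  expect_true(isTRUE(win$window_only))

  shifted <- pair$treatment
  shifted$trial <- trial_record("treatment", 2, shifted$trial$end_day + 1,
                                shifted$trial$milk_yield_daily,
                                shifted$trial$fat_pct, shifted$trial$protein_pct,
                                shifted$trial$dmi_daily)
  expect_error(supplementation_window_compare(pair$control, shifted, gen$ef),
               class = "dfp_validation_error")
})

test_that("annual differences are diluted window differences on random fixtures", {
  # outside-window behaviour is equalized (shared reference, composition
  # effects off), so the full-year accounting can only shrink the contrast
  for (seed in 1:6) {
    sc <- synthetic_scenario(seed = seed, n_trials = 1,
                             fat_effect_sd = 0, protein_effect_sd = 0,
                             my_effect_sd = 0.05, dmi_effect_sd = 0.05)
    gen <- generate_scenario(sc)
    pair <- gen$pairs[[1]]
    # allocation held fixed so the dilution is purely the accounting window
    ctl <- farm_system(pair$control$trial, pair$control$reference,
                       allocation = "none")
    trt <- farm_system(pair$treatment$trial, pair$treatment$reference,
                       allocation = "none")
    res_ann <- assess_pair(ctl, trt, gen$ef)
    cmp_ann <- compare(res_ann$control, res_ann$treatment)
    cmp_win <- supplementation_window_compare(ctl, trt, gen$ef)
    expect_true(all(abs(cmp_ann$table$diff_pct) <=
                      abs(cmp_win$table$diff_pct) + 1e-9))
  }
})

test_that("degenerate distributions collapse the Monte Carlo to the point estimate", {
  pr <- tiny_pair(seed = 31, gsd_range = c(1, 1))
  mc <- monte_carlo(pr$control, pr$treatment, pr$ef, n_iter = 25, seed = 99)
  for (k in seq_along(mc$summary$category)) {
    expect_equal(unname(mc$draws[, k]),
                 rep(mc$summary$point[k], 25), tolerance = 1e-9)
  }
})

test_that("Monte Carlo runs are reproducible from the seed", {
  pr <- tiny_pair(seed = 31)
  a <- monte_carlo(pr$control, pr$treatment, pr$ef, n_iter = 40, seed = 7)
  b <- monte_carlo(pr$control, pr$treatment, pr$ef, n_iter = 40, seed = 7)
  expect_identical(a$draws, b$draws)
  c2 <- monte_carlo(pr$control, pr$treatment, pr$ef, n_iter = 40, seed = 8)
  expect_false(identical(a$draws, c2$draws))
  expect_error(monte_carlo(pr$control, pr$treatment, pr$ef, n_iter = 0, seed = 1),
               class = "dfp_validation_error")
})

test_that("jointly rescaling the EF table cancels out of fully table-driven categories", {
  pr <- tiny_pair(seed = 33)
  ef2 <- pr$ef; ef2$value <- ef2$value * 2
  res1 <- assess_pair(pr$control, pr$treatment, pr$ef)
  res2 <- assess_pair(pr$control, pr$treatment, ef2)
  d1 <- compare(res1$control, res1$treatment)$table
  d2 <- compare(res2$control, res2$treatment)$table
  for (cat in c("LU", "WU", "RU", "FEU")) {
    expect_equal(d1$diff_pct[d1$category == cat],
                 d2$diff_pct[d2$category == cat], tolerance = 1e-9)
  }
})

test_that("the paired Monte Carlo median agrees with the deterministic difference", {
  uk <- fixtures$pairs$uk
  mc <- monte_carlo(uk$control, uk$treatment, fixtures$ef, fixtures$cf,
                    n_iter = 400, seed = 2024)
  cc <- mc$summary[mc$summary$category == "CC", ]
  se_median <- 1.2533 * stats::sd(mc$draws[, "CC"]) / sqrt(nrow(mc$draws))
  expect_lt(abs(cc$median - cc$point), 3 * se_median + 1e-6)
  expect_true(cc$q025 <= cc$median && cc$median <= cc$q975)
})

test_that("one-at-a-time sensitivities are exact for linear parameters", {
  fr <- fixtures$pairs$french
  sens <- sensitivity_oat(fr$control, fr$treatment, fixtures$ef, fixtures$cf,
                          parameters = c("ym", "milk_yield_daily", "dmi_daily"),
                          perturbation = 0.05)
  # the Ym elasticity equals the modeled enteric methane share of the total
  pr <- annualize(fr$control$trial, fr$control$reference)
  flows <- emission_flows(pr, fr$control$reference, fr$control$params,
                          fixtures$ef, item_map = fr$control$item_map)
  res <- assess_system(fr$control, fixtures$ef, fixtures$cf)
  share <- flows$ch4_enteric * fixtures$cf$gwp_ch4 * res$af /
    pr$fpcm_annual / res$total[["CC"]]
  expect_equal(sens$elasticity_cc_total[sens$parameter == "ym"], share,
               tolerance = 1e-6)

  zero <- sensitivity_oat(fr$control, fr$treatment, fixtures$ef, fixtures$cf,
                          parameters = c("ym", "dmi_daily"), perturbation = 0)
  expect_true(all(zero$elasticity_cc_total == 0))
  expect_error(sensitivity_oat(fr$control, fr$treatment, fixtures$ef,
                               fixtures$cf, parameters = "no_such_knob"),
               class = "dfp_validation_error")
})

test_that("sensitivity rankings are stable under halving the perturbation", {
  fr <- fixtures$pairs$french
  pars <- c("ym", "milk_yield_daily", "dmi_daily", "mcf")
  s1 <- sensitivity_oat(fr$control, fr$treatment, fixtures$ef, fixtures$cf,
                        parameters = pars, perturbation = 0.05)
  s2 <- sensitivity_oat(fr$control, fr$treatment, fixtures$ef, fixtures$cf,
                        parameters = pars, perturbation = 0.025)
  expect_identical(s1$parameter, s2$parameter)
})
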