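test_that("Tier-2 enteric methane matches hand evaluation and scales with energy", {
  p <- emission_params(ym = 6.5)
  # 122122 MJ x 0.065 / 55.65
  expect_equal(as.numeric(enteric_ch4(122122, p)), 142.6499, tolerance = 1e-4)
  expect_equal(as.numeric(enteric_ch4(0, p)), 0)
  expect_identical(attr(enteric_ch4(1000, p), "provenance"), "model")
  # homogeneity of degree 1 in gross energy
  expect_equal(as.numeric(enteric_ch4(2 * 122122, p)),
               2 * as.numeric(enteric_ch4(122122, p)), tolerance = 1e-12)
})

test_that("the annual enteric model equals a day-by-day summation", {
  p <- emission_params()
  ge <- 99464
  daily <- rep(ge / 365, 365)
  brute <- sum(daily * (p$ym / 100) / p$ch4_energy_density)
  expect_equal(as.numeric(enteric_ch4(ge, p)), brute, tolerance = 1e-12)
})

test_that("a measured methane record overrides the model inside its window only", {
  p <- emission_params()
  ge <- 122122; ge_win <- ge * 2868 / 6619
  out <- enteric_ch4(ge, p, measured_daily = 0.467, measured_days = 120,
                     ge_measured_window = ge_win)
  expect_identical(attr(out, "provenance"), "measured+model")
  expect_equal(as.numeric(out),
               0.467 * 120 + (ge - ge_win) * 0.065 / 55.65, tolerance = 1e-9)
})

test_that("the measured override changes methane flows and nothing else", {
  uk <- fixtures$pairs$uk$control
  pr <- annualize(uk$trial, uk$reference)
  with_meas <- emission_flows(pr, uk$reference, uk$params, fixtures$ef,
                              item_map = uk$item_map)
  pr2 <- pr; pr2$measured_ch4_daily <- NULL
  without <- emission_flows(pr2, uk$reference, uk$params, fixtures$ef,
                            item_map = uk$item_map)
  expect_false(isTRUE(all.equal(with_meas$ch4_enteric, without$ch4_enteric)))
  for (f in c("ch4_manure", "n2o_direct", "n2o_indirect", "nh3", "n_leached",
              "co2_direct", "nmvoc", "pm10", "pm25")) {
    expect_identical(with_meas[[f]], without[[f]])
  }
})

test_that("manure methane follows VS x B0 x density x MCF", {
  p <- emission_params(b0 = 0.24, mcf = 0.10)
  expect_equal(manure_ch4(1000, p), 1000 * 0.24 * 0.67 * 0.10)
  expect_equal(manure_ch4(0, p), 0)
  # linear in MCF
  p2 <- emission_params(b0 = 0.24, mcf = 0.20)
  expect_equal(manure_ch4(1000, p2), 2 * manure_ch4(1000, p))
  expect_error(manure_ch4(1000, p, manure_system_label = ""),
               class = "dfp_validation_error")
})

test_that("volatile solids derive from undigested plus urinary energy", {
  p <- emission_params(digestibility = 0.7, urinary_energy_fraction = 0.04,
                       ash_fraction = 0.08, ge_per_kg_dm = 18.45)
  expect_equal(volatile_solids(18450, p), 18450 * 0.34 * 0.92 / 18.45)
  expect_equal(volatile_solids(0, p), 0)
})

test_that("manure N2O follows the stoichiometric split of excreted nitrogen", {
  p <- emission_params(ef3 = 0.02, frac_gas = 0.3, ef4 = 0.01,
                       frac_leach = 0.3, ef5 = 0.0075)
  out <- manure_n2o(100, p)
  expect_equal(out$n2o_direct, 100 * 0.02 * 44 / 28, tolerance = 1e-12)
  expect_equal(out$n2o_indirect,
               (100 * 0.3 * 0.01 + 100 * 0.3 * 0.0075) * 44 / 28,
               tolerance = 1e-12)
  expect_equal(out$nh3, 100 * 0.3 * 17 / 14, tolerance = 1e-12)

  zero <- manure_n2o(0, p)
  expect_true(all(unlist(zero) == 0))
  p0 <- emission_params(frac_gas = 0, frac_leach = 0)
  expect_equal(manure_n2o(50, p0)$n2o_indirect, 0)
  expect_error(manure_n2o(-1, p), class = "dfp_validation_error")
})

test_that("utility CO2 sums quantity times factor and names unresolved items", {
  ef <- ef_table(c("fuel", "bedding"), c("CC", "CC"), c(0.3, 0.1))
  ref0 <- reference_system("x", 8000, utilities = c(energy = 100, water = 0))
  expect_equal(utility_co2(ref0, ef), 0)  # energy/water report elsewhere
  ref1 <- reference_system("x", 8000, utilities = c(fuel = 1000))
  expect_equal(utility_co2(ref1, ef), 300)
  ref2 <- reference_system("x", 8000, utilities = c(diesel = 10))
  expect_error(utility_co2(ref2, ef), class = "dfp_resolution_error")
})

test_that("every flow is homogeneous of degree one in its driver", {
  p <- emission_params()
  for (x in c(500, 5000)) {
    expect_equal(as.numeric(enteric_ch4(3 * x, p)),
                 3 * as.numeric(enteric_ch4(x, p)), tolerance = 1e-12)
    expect_equal(manure_ch4(3 * x, p), 3 * manure_ch4(x, p), tolerance = 1e-12)
    n3 <- manure_n2o(3 * x, p); n1 <- manure_n2o(x, p)
    expect_equal(unlist(n3), 3 * unlist(n1), tolerance = 1e-12)
  }
})
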