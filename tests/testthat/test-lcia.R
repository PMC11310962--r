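test_that("the biophysical allocation factor follows 1 - 6.04 Mmeat/Mmilk", {
  expect_equal(allocation_factor(200, 10000), 1 - 6.04 * 0.02)
  expect_equal(allocation_factor(0, 8000), 1)
  expect_error(allocation_factor(2000, 10000), class = "dfp_numerical_error")
  expect_error(allocation_factor(100, 0), class = "dfp_validation_error")
})

test_that("milk and meat allocation are exact complements", {
  withr::with_seed(11, {
    for (i in 1:25) {
      m_milk <- runif(1, 6000, 13000)
      m_meat <- runif(1, 0, m_milk / 6.04 * 0.9)
      af <- allocation_factor(m_meat, m_milk)
      am <- 1 - af
      expect_equal(af + am, 1, tolerance = 1e-15)
      expect_true(af > 0 && af <= 1)
    }
  })
})

test_that("more corrected milk at equal meat mass allocates more to milk", {
  # the conservative-allocation property of the paired design
  withr::with_seed(12, {
    for (i in 1:20) {
      m_meat <- runif(1, 100, 300)
      fpcm_c <- runif(1, 7000, 12000)
      fpcm_t <- fpcm_c * runif(1, 1, 1.1)
      expect_gte(allocation_factor(m_meat, fpcm_t),
                 allocation_factor(m_meat, fpcm_c))
    }
  })
})

test_that("all-zero flows characterize to all-zero impacts", {
  flows0 <- structure(list(
    ch4_enteric = 0, ch4_manure = 0, n2o_direct = 0, n2o_indirect = 0,
    nh3 = 0, n_leached = 0, co2_direct = 0, nmvoc = 0, pm10 = 0, pm25 = 0,
    ch4_provenance = "model"
  ), class = "emission_flows")
  tr <- trial_record("control", 1, 100, 30, 4, 3.3, 20)
  ref <- reference_system("x", 9000)
  pr <- annualize(tr, ref)
  ef0 <- ef_table("anything", "CC", 0)
  feed0 <- feed_impacts(pr, ef0, compound_share = 0.4,
                        item_map = c(compound = "anything", roughage = "anything2",
                                     luc = "luc0", additive = "add0"))
  res <- characterize(flows0, feed0, characterization_factors(), pr, af = 0.9)
  expect_true(all(res$breakdown == 0))
  expect_true(all(res$total == 0))
})

test_that("the breakdown sums to the total in every category for generated systems", {
  for (seed in 1:4) {
    gen <- generate_scenario(synthetic_scenario(seed = seed, n_trials = 2))
    for (pair in gen$pairs) {
      res <- assess_pair(pair$control, pair$treatment, gen$ef)
      for (r in res) {
        expect_equal(unname(colSums(r$breakdown)), unname(r$total),
                     tolerance = 1e-12)
        expect_true(all(r$breakdown >= 0))
      }
    }
  }
})

test_that("impacts scale linearly with the allocation factor", {
  pr <- tiny_pair()
  sysl <- pr$control
  res1 <- assess_system(sysl, pr$ef)
  sysl$reference$herd_coproduct_liveweight <- 0
  res_full <- assess_system(sysl, pr$ef)  # af = 1
  expect_equal(res1$breakdown, res_full$breakdown * res1$af, tolerance = 1e-12)
})

test_that("zero corrected milk or an invalid allocation factor is an error", {
  flows0 <- structure(list(ch4_enteric = 1, ch4_manure = 0, n2o_direct = 0,
                           n2o_indirect = 0, nh3 = 0, n_leached = 0,
                           co2_direct = 0, nmvoc = 0, pm10 = 0, pm25 = 0,
                           ch4_provenance = "model"),
                      class = "emission_flows")
  tr <- trial_record("control", 1, 100, 30, 4, 3.3, 20)
  pr <- annualize(tr, reference_system("x", 9000))
  feed <- feed_impacts(pr, ef_table("compound_feed", "CC", 0.5))
  pr_bad <- pr; pr_bad$fpcm_annual <- 0
  expect_error(characterize(flows0, feed, characterization_factors(), pr_bad, 1),
               class = "dfp_numerical_error")
  expect_error(characterize(flows0, feed, characterization_factors(), pr, 1.2),
               class = "dfp_validation_error")
})

test_that("contribution analysis reproduces the published feed-compound share", {
  res <- published_impact_results(published, "french")
  shares <- contribution_analysis(res$control, "CC")
  expect_equal(shares[["feed_compounds"]], 25.39, tolerance = 0.005)
  expect_equal(round(shares[["feed_compounds"]], 1), 25.4)
  expect_equal(sum(shares), 100, tolerance = 1e-9)
})

test_that("contribution percentages are scale-invariant and complete", {
  pr <- tiny_pair(seed = 5)
  res <- assess_system(pr$control, pr$ef)
  shares <- contribution_analysis(res, "CC")
  expect_equal(sum(shares), 100, tolerance = 1e-9)

  scaled <- res
  scaled$breakdown <- res$breakdown * 7.3
  scaled$total <- res$total * 7.3
  expect_equal(contribution_analysis(scaled, "CC"), shares, tolerance = 1e-12)

  solo <- impact_result(c(on_farm_ch4 = 0.42), category = "CC")
  expect_equal(contribution_analysis(solo, "CC")[["on_farm_ch4"]], 100)
})
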