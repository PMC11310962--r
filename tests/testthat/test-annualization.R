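test_that("the FPCM correction reproduces hand-computed reference values", {
  # frozen by direct evaluation of milk x (0.1226 fat + 0.0776 protein + 0.2534)
  expect_equal(fpcm(11963, 3.90, 3.25), 11768.48, tolerance = 1e-6)
  expect_equal(fpcm(8639.2, 3.84, 3.35), 8502.217, tolerance = 1e-6)
  expect_equal(fpcm(8630, 3.81, 3.35), 8461.42, tolerance = 1e-5)
  expect_equal(fpcm(8836, 4.33, 3.06), 9027.865, tolerance = 1e-6)
  expect_identical(fpcm(0, 4.0, 3.3), 0)
  expect_error(fpcm(100, 11, 3), class = "dfp_validation_error")
})

test_that("FPCM is linear in milk and collapses to 0.2534 at zero composition", {
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- runif(1, 0, 5000); b <- runif(1, 0, 5000)
      f <- runif(1, 3, 5); p <- runif(1, 2.8, 3.6)
      expect_equal(fpcm(a + b, f, p), fpcm(a, f, p) + fpcm(b, f, p),
                   tolerance = 1e-12)
    }
  })
  expect_equal(fpcm(1, 0, 0), 0.2534)
})

test_that("outside-window intake extrapolation is proportional in milk", {
  expect_equal(extrapolate_fi_outside(2868, 6263, 5700), 3151.278,
               tolerance = 1e-4)
  # equal yields leave intake unchanged
  expect_equal(extrapolate_fi_outside(1234.5, 4000, 4000), 1234.5)
  # direct evaluation on the French control values (published table rounds
  # its own cell to 2427)
  expect_equal(extrapolate_fi_outside(2365.2, 4206, 4093.2), 2430.38,
               tolerance = 1e-2)
  expect_error(extrapolate_fi_outside(2868, 6263, 0),
               class = "dfp_numerical_error")
})

test_that("annualization reproduces the published annual intake decomposition", {
  fr <- fixtures$pairs$french
  pr_c <- annualize(fr$control$trial, fr$control$reference)
  expect_equal(pr_c$fi_annual, 2365.2 + 2427 + 600, tolerance = 1e-9)
  pr_t <- annualize(fr$treatment$trial, fr$treatment$reference,
                    control_trial = fr$control$trial)
  expect_equal(pr_t$fi_annual, 5554.2, tolerance = 1e-9)

  uk <- fixtures$pairs$uk
  expect_equal(annualize(uk$control$trial, uk$control$reference)$fi_annual,
               6619, tolerance = 1e-9)
  expect_equal(annualize(uk$treatment$trial, uk$treatment$reference,
                         control_trial = uk$control$trial)$fi_annual,
               6631, tolerance = 1e-9)

  de <- fixtures$pairs$german
  pr_de <- annualize(de$control$trial, de$control$reference)
  expect_equal(pr_de$fi_annual, 6147.8, tolerance = 0.5)  # table prints 6148
  # decomposition is exact, not approximate
  for (pr in list(pr_c, pr_t, pr_de)) {
    expect_identical(pr$fi_annual, pr$fi_trial + pr$fi_outside + pr$fi_dry)
  }
})

test_that("trial-window feed efficiency matches the consistent published cells", {
  de <- fixtures$pairs$german
  expect_equal(round(annualize(de$control$trial, de$control$reference)$fe_trial, 2),
               1.53)
  expect_equal(round(annualize(de$treatment$trial, de$treatment$reference,
                               control_trial = de$control$trial)$fe_trial, 1),
               1.6)
  fr <- fixtures$pairs$french
  expect_equal(round(annualize(fr$control$trial, fr$control$reference)$fe_trial, 2),
               1.75)
})

test_that("a trial spanning the whole lactation leaves nothing to extrapolate", {
  tr <- trial_record("control", 1, 305, 30, 4, 3.3, 20)
  ref <- reference_system("x", annual_reference_milk = 9000)
  pr <- annualize(tr, ref)
  expect_equal(pr$fi_outside, 0)
  expect_equal(pr$my_outside, 0)
  expect_equal(pr$milk_annual, 30 * 305)
  expect_error(annualize(trial_record("control", 1, 306, 30, 4, 3.3, 20),
                         ref, ),
               class = "dfp_validation_error")
})

test_that("identical trial records annualize to identical profiles", {
  mk <- function(label) trial_record(label, 1, 120, 40, 4, 3.3, 22,
                                     additive_dose = 0)
  ref <- reference_system("x", 9500, my_outside_trial = 5000,
                          herd_coproduct_liveweight = 200)
  pc <- annualize(mk("control"), ref)
  pt <- annualize(mk("treatment"), ref, control_trial = mk("control"))
  expect_equal(pc, pt)
})

test_that("annual additive mass is dose times days, in kilograms", {
  uk_t <- fixtures$pairs$uk$treatment
  pr <- annualize(uk_t$trial, uk_t$reference,
                  control_trial = fixtures$pairs$uk$control$trial)
  expect_equal(pr$additive_mass_annual, 10 * 120 / 1000)
})
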