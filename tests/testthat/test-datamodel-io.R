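test_that("constructors reject single-field invariant violations by name", {
  ok <- list(group_label = "control", start_day = 1, end_day = 108,
             milk_yield_daily = 37.9, fat_pct = 4.29, protein_pct = 3,
             dmi_daily = 21.9)
  expect_s3_class(do.call(trial_record, ok), "trial_record")

  bad_cases <- list(
    list(fat_pct = 0), list(fat_pct = 12), list(protein_pct = 0),
    list(milk_yield_daily = -1), list(dmi_daily = 0),
    list(additive_dose = -5), list(end_day = 0), list(n_cows = 0.5)
  )
  for (mod in bad_cases) {
    args <- utils::modifyList(ok, mod)
    err <- tryCatch(do.call(trial_record, args), error = identity)
    expect_s3_class(err, "dfp_validation_error")
    expect_true(names(mod) %in% err$fields || length(err$fields) > 0)
  }

  expect_error(reference_system("x", 8000, lactation_days = 320, dry_days = 60),
               class = "dfp_validation_error")
  expect_error(diet(c("a", "b"), c(0.6, 0.5)), class = "dfp_validation_error")
})

test_that("the trial window is 1-based inclusive", {
  tr <- trial_record("control", 109, 200, 34.1, 3.84, 3.35, 21.9)
  expect_identical(tr$duration_days, 200L - 109L + 1L)
  tr2 <- trial_record("control", 1, 108, 37.9, 4.29, 3, 21.9)
  expect_identical(tr2$duration_days, 108L)
})

test_that("EF table rejects duplicates and negatives, defaults gsd to 1", {
  expect_error(ef_table(c("a", "a"), c("CC", "CC"), c(1, 2)),
               class = "dfp_validation_error")
  expect_error(ef_table("a", "CC", -0.1), class = "dfp_validation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_key,category,value,gsd",
               "additive,CC,2.10,",
               "compound_feed,CC,0.5,1.3"), path)
  ef <- read_ef_table(path)
  expect_equal(ef_factor(ef, "additive", "CC"), 2.10)
  expect_equal(ef$gsd[ef$item_key == "additive"], 1)
  expect_equal(ef$gsd[ef$item_key == "compound_feed"], 1.3)
})

test_that("a generated emission-factor table resolves every item-category cell", {
  ef <- withr::with_seed(7, synthetic_ef_table(n_items = 50))
  items <- unique(ef$item_key)
  expect_length(items, 58)  # 50 generic + 8 core roles
  expect_identical(nrow(ef), 58L * 8L)
  for (cat in category_keys()) {
    vals <- vapply(items, function(i) ef_factor(ef, i, cat), numeric(1))
    expect_true(all(is.finite(vals)) && all(vals >= 0))
  }
})

test_that("farm-system serialization round-trips the trial fixtures", {
  for (cc in names(fixtures$pairs)) {
    for (grp in c("control", "treatment")) {
      sys <- fixtures$pairs[[cc]][[grp]]
      path <- withr::local_tempfile(fileext = ".yaml")
      write_farm_system(sys, path)
      back <- read_farm_system(path)
      expect_equal(back, sys, tolerance = 1e-12)
    }
  }
})

test_that("serialization round-trips randomized valid systems and EF tables", {
  for (seed in 1:5) {
    gen <- generate_scenario(synthetic_scenario(seed = seed, n_trials = 2))
    for (pair in gen$pairs) {
      path <- withr::local_tempfile(fileext = ".yaml")
      write_farm_system(pair$treatment, path)
      expect_equal(read_farm_system(path), pair$treatment, tolerance = 1e-12)
    }
    ef_path <- withr::local_tempfile(fileext = ".csv")
    write_ef_table(gen$ef, ef_path)
    expect_equal(read_ef_table(ef_path), gen$ef, tolerance = 1e-12)
  }
})

test_that("reading a farm system without schema_version fails", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("trial:\n  group_label: control", path)
  expect_error(read_farm_system(path), class = "dfp_validation_error")
  expect_error(read_farm_system("no/such/file.yaml"),
               class = "dfp_validation_error")
})

test_that("reports write a machine file that parses back and a labeled table", {
  p <- fixtures$pairs$uk
  res <- assess_pair(p$control, p$treatment, fixtures$ef, fixtures$cf)
  rep <- compare(res$control, res$treatment)

  stem <- withr::local_tempfile()
  paths <- write_report(rep, stem)
  back <- read_report(paths[["json"]])
  expect_equal(back$table, rep$table, tolerance = 1e-12)
  expect_equal(back$breakdown_cc, rep$breakdown_cc, tolerance = 1e-12)

  txt <- readLines(paths[["txt"]])
  labels <- c("Feed compounds", "Roughages", "On farm CO2", "On-farm N2O",
              "On farm CH4", "Energy at Farm", "Water at Farm", "Additive",
              "Land use change")
  for (lab in labels) expect_true(any(startsWith(txt, lab)))

  expect_error(write_report(list(), withr::local_tempfile()),
               class = "dfp_validation_error")
})

test_that("pairing a system with an incomplete EF table names the missing keys", {
  pr <- tiny_pair()
  ef_small <- fixtures$ef  # lacks the generic compound_feed/roughage keys
  err <- tryCatch(assess_system(pr$control, ef_small), error = identity)
  expect_s3_class(err, "dfp_resolution_error")
  expect_true(any(grepl("compound_feed", err$keys)))
})
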