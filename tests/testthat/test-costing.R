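test_that("fee schedules load, and malformed schedules are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,category,unit_cost_tzs,modality,variant,ward",
               "consult_emergency,consult_specialist,20000,,,",
               "img_xr,imaging,15000,xray,unilateral,",
               "bed_gen,admission_day,10000,,,general"), path)
  sched <- load_fee_schedule(path)
  expect_equal(nrow(sched), 3)
  expect_s3_class(sched, "fintox_fee_schedule")

  writeLines(c("code,category,unit_cost_tzs,modality,variant,ward",
               "a,consumable,-5,,,"), path)
  expect_error(load_fee_schedule(path), class = "fintox_validation_error")

  writeLines(c("code,category,unit_cost_tzs,modality,variant,ward",
               "a,consumable,5,,,", "a,consumable,7,,,"), path)
  expect_error(load_fee_schedule(path), "a", class = "fintox_validation_error")

  writeLines(c("code,category,unit_cost_tzs", "a,consumable,5"), path)
  expect_error(load_fee_schedule(path), "modality", class = "fintox_schema_error")

  expect_error(as_fee_schedule(data.frame(
    code = "x", category = "imaging", unit_cost_tzs = 5)),
    class = "fintox_validation_error")  # imaging without modality
})

test_that("item costs resolve exactly, with mean substitution for unknowns", {
  sched <- tiny_schedule()
  # known item, quantity 2
  expect_equal(resolve_item_cost(sched, list(
    category = "procedure_nonsurgical", code_or_modality = "proc_fluids",
    variant = NA, laterality = NA, quantity = 2)), 24000)
  # unknown-subtype MRI: mean of 100,000 and 300,000
  expect_equal(resolve_item_cost(sched, list(
    category = "imaging", code_or_modality = "mri",
    variant = "unknown", laterality = "unknown", quantity = 1)), 200000)
  # unknown laterality: mean of unilateral 50,000 and bilateral 80,000
  expect_equal(resolve_item_cost(sched, list(
    category = "imaging", code_or_modality = "xray",
    variant = "unknown", laterality = "unknown", quantity = 1)), 65000)
  # known laterality narrows to the matching item
  expect_equal(resolve_item_cost(sched, list(
    category = "imaging", code_or_modality = "xray",
    variant = "unknown", laterality = "bilateral", quantity = 1)), 80000)
  # absent modality is unresolvable
  expect_error(resolve_item_cost(sched, list(
    category = "imaging", code_or_modality = "pet",
    variant = "unknown", laterality = "unknown", quantity = 1)),
    class = "fintox_unresolvable_item_error")
  expect_error(resolve_item_cost(sched, list(
    category = "imaging", code_or_modality = "mri",
    variant = "unknown", laterality = "unknown", quantity = 0)),
    class = "fintox_validation_error")
})

test_that("substituted costs always lie within the candidate price range", {
  set.seed(101)
  for (rep in 1:20) {
    prices <- round(runif(4, 1e4, 5e5))
    sched <- as_fee_schedule(tibble::tibble(
      code = paste0("m", 1:4), category = "imaging",
      unit_cost_tzs = prices, modality = "mri",
      variant = paste0("v", 1:4), ward = NA))
    got <- resolve_item_cost(sched, list(
      category = "imaging", code_or_modality = "mri",
      variant = "unknown", laterality = "unknown", quantity = 1))
    expect_gte(got, min(prices))
    expect_lte(got, max(prices))
  }
})

test_that("stay and death expenses follow the ward rates and death items", {
  sched <- tiny_schedule()
  expect_equal(compute_stay_cost(sched, 0, 0), 0)
  expect_equal(compute_stay_cost(sched, 3, 2), 3 * 10000 + 2 * 50000)
  expect_error(compute_stay_cost(sched, -1, 0), class = "fintox_validation_error")
  no_icu <- as_fee_schedule(tiny_schedule()[tiny_schedule()$ward %in% c(NA, "general"), ])
  expect_error(compute_stay_cost(no_icu, 0, 1),
               class = "fintox_unresolvable_item_error")

  expect_equal(compute_death_cost(sched, FALSE), 0)
  expect_equal(compute_death_cost(sched, TRUE), 10000)
  no_bag <- as_fee_schedule(sched[sched$code != "body_bag", ])
  expect_error(compute_death_cost(no_bag, TRUE), "body_bag",
               class = "fintox_unresolvable_item_error")
})

test_that("a service-free encounter is billed the emergency consult only", {
  sched <- tiny_schedule()
  bd <- compute_oop(sched, list(days_general = 0, days_icu = 0, died = FALSE))
  expect_equal(bd$total_oop, 20000)
  expect_equal(bd$consultations, 20000)
  expect_equal(bd$procedures + bd$imaging + bd$stay + bd$consumables + bd$death, 0)
})

test_that("cohort costing matches a flat line-item enumeration", {
  sched <- default_fee_schedule()
  coh <- generate_cohort(cohort_params(n_patients = 50, seed = 3),
                         schedule = sched)
  got <- cost_cohort(sched, coh$encounters, coh$services)
  for (i in seq_len(50)) {
    pid <- coh$encounters$patient_id[i]
    svc <- coh$services[coh$services$patient_id == pid, ]
    expected <- oracle_oop_total(sched, as.list(coh$encounters[i, ]), svc)
    expect_equal(got$total_oop[i], expected, tolerance = 1e-10)
  }
  # component additivity
  comp_sum <- got$consultations + got$procedures + got$imaging +
    got$stay + got$consumables + got$death
  expect_true(all(abs(comp_sum - got$total_oop) < 1e-6))
  # determinism: identical encounters give identical breakdowns
  again <- cost_cohort(sched, coh$encounters, coh$services)
  expect_identical(got, again)
})

test_that("adding a positively-priced service never decreases the total", {
  sched <- tiny_schedule()
  enc <- list(patient_id = "P1", days_general = 2, days_icu = 0, died = FALSE)
  svc <- tibble::tibble(patient_id = "P1", category = "imaging",
                        code_or_modality = "mri", variant = "unknown",
                        laterality = "unknown", quantity = 1)
  base <- compute_oop(sched, enc, svc)$total_oop
  for (extra_code in c("proc_fluids", "surg_fix", "cons_saline")) {
    svc2 <- rbind(svc, tibble::tibble(
      patient_id = "P1", category = sched$category[sched$code == extra_code],
      code_or_modality = extra_code, variant = NA_character_,
      laterality = NA_character_, quantity = 1))
    expect_gt(compute_oop(sched, enc, svc2)$total_oop, base)
  }
})

test_that("TZS amounts convert to USD at the study rate", {
  expect_equal(convert_tzs_to_usd(2339, 2339), 1)
  expect_equal(convert_tzs_to_usd(476792.7, 2339, round_to = "integer"), 204)
  expect_equal(convert_tzs_to_usd(98387.1, 2339, round_to = "integer"), 42)
  expect_error(convert_tzs_to_usd(100, 0), class = "fintox_validation_error")
  expect_error(convert_tzs_to_usd(100, -5), class = "fintox_validation_error")
})
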