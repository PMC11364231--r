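test_that("median and IQR use linear-interpolation quantiles", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), c(median = 3, iqr = 2))
  expect_equal(median_iqr(7), c(median = 7, iqr = 0))
  expect_equal(median_iqr(rep(4.2, 9)), c(median = 4.2, iqr = 0))
  expect_error(median_iqr(numeric(0)), class = "fintox_validation_error")
})

test_that("prevalences reproduce the headline percentages", {
  expect_equal(prevalence(rep(c(TRUE, FALSE), c(49, 29))), 62.8)
  expect_equal(prevalence(rep(c(TRUE, NA), c(67, 11)), denominator = 78), 85.9)
  expect_equal(prevalence(rep(FALSE, 40)), 0)
  expect_error(prevalence(logical(0), denominator = 0),
               class = "fintox_validation_error")
})

test_that("median ratios match the printed table arithmetic", {
  expect_equal(ratio_of_medians(157894.7, 62500), 2.53)
  expect_equal(ratio_of_medians(603585.5, 104585.5), 5.77)
  expect_equal(ratio_of_medians(c(5, 7, 9), c(5, 7, 9)), 1)
  expect_error(ratio_of_medians(c(1, 2), c(0, 0)),
               class = "fintox_undefined_ratio_error")
})

test_that("group comparisons pick Welch t, ANOVA, or chi-square as appropriate", {
  g <- rep(c("a", "b"), each = 30)
  x <- rep(c(1, 5, 9), 20)
  same <- group_compare(c(x, x)[1:60], g)
  expect_equal(same$method, "welch_t")
  expect_lt(abs(same$statistic), 1e-8)
  expect_gt(same$p_value, 0.99)

  set.seed(55)
  far <- group_compare(c(rnorm(50), rnorm(50, 5)), rep(c("a", "b"), each = 50))
  expect_lt(far$p_value, 0.001)

  three <- group_compare(rnorm(90), rep(c("a", "b", "c"), each = 30))
  expect_equal(three$method, "anova_f")
  expect_gt(three$p_value, 0.001)

  cat_cmp <- group_compare(rep(c("x", "y"), 25), rep(c("g1", "g2"), each = 25))
  expect_equal(cat_cmp$method, "chi_square")

  expect_error(group_compare(rnorm(5), rep("a", 5)),
               class = "fintox_degenerate_group_error")
})

test_that("the Welch test holds its nominal 5% size on equal-mean groups", {
  set.seed(77)
  n_rep <- 1000
  rejections <- 0
  for (r in seq_len(n_rep)) {
    p <- group_compare(rnorm(30), rep(c("a", "b"), each = 15))$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2 * se)
})

test_that("stratified tables have coherent strata, denominators, and closure", {
  coh <- generate_cohort(cohort_params(n_patients = 78, seed = 13,
                                       target_any_che = 49 / 78))
  res <- coh$labels
  tab <- build_stratified_table(coh, res, "che")
  sizes <- attr(tab, "stratum_sizes")
  expect_equal(unname(sizes[["any"]]), 49)
  expect_equal(unname(sizes[["none"]]), 29)
  expect_equal(unname(sizes[["overall"]]), 78)

  # per-threshold strata are subsets of "any"
  for (cl in c("che_10_te", "che_25_te", "che_40_nse")) {
    expect_true(all(res$any_che[res[[cl]]]))
    expect_lte(sizes[[cl]], sizes[["any"]])
  }

  # within each variable and stratum, percentages (unknowns included) close
  for (v in unique(tab$variable[tab$category != "median_iqr"])) {
    for (s in unique(tab$stratum)) {
      sub <- tab[tab$variable == v & tab$stratum == s, ]
      if (sizes[[s] ] > 0) {
        expect_lt(abs(sum(sub$pct) - 100), 0.1 + 1e-9)
        expect_equal(sum(sub$n), unname(sizes[[s]]))
      }
    }
  }

  # the IMP table drops income-missing patients from its strata
  tab_imp <- build_stratified_table(coh, res, "imp")
  sizes_imp <- attr(tab_imp, "stratum_sizes")
  n_missing <- sum(coh$households$income_missing)
  expect_equal(unname(sizes_imp[["any"]] + sizes_imp[["none"]]), 78 - n_missing)
  expect_equal(unname(sizes_imp[["overall"]]), 78)

  md <- render_stratified_markdown(tab)
  expect_match(md, "p<0.05", fixed = TRUE)
  expect_match(md, "\\| sex \\|")
})

test_that("a single-stratum cohort renders n = 0 rows for the other stratum", {
  sched <- tiny_schedule()
  hh <- make_households(4, te = 1e6, food = 5e5, income = 1e8)
  enc <- tibble::tibble(patient_id = hh$patient_id, age = 30, sex = "male",
                        education = "5-10", region = "other",
                        marital_status = "single", occupation = "farmer",
                        insurance = "uninsured",
                        mechanism = "rti", hospitalized = FALSE, surgery = FALSE,
                        died = FALSE, days_general = 0, days_icu = 0)
  svc <- tibble::tibble(patient_id = hh$patient_id, category = "procedure_surgical",
                        code_or_modality = "surg_fix", variant = NA_character_,
                        laterality = NA_character_, quantity = 1)
  costs <- cost_cohort(sched, enc, svc)
  res <- toxicity_table(hh, costs)
  expect_true(all(res$any_che))  # 470,000 OOP against 1M TE trips 10% and 25%
  cohort <- list(households = hh, encounters = enc)
  tab <- build_stratified_table(cohort, res, "che")
  expect_equal(unname(attr(tab, "stratum_sizes")[["none"]]), 0)
  expect_equal(unique(tab$n[tab$stratum == "none"]), 0)
})
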