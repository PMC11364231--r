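test_that("OECD-modified adult equivalents match the closed form", {
  expect_equal(adult_equivalents(1, 0), 1.0)
  expect_equal(adult_equivalents(2, 0), 1.5)
  expect_equal(adult_equivalents(2, 2), 2.1)
  expect_equal(adult_equivalents(c(1, 3), c(2, 4)),
               c(1 + 0.6, 1 + 1 + 1.2))
  expect_error(adult_equivalents(0, 1), class = "fintox_validation_error")
})

test_that("subsistence expenditure averages food spending in the 45th-55th consumption window", {
  # constant cohort: the window mean is the common food value
  hh <- make_households(10, te = 5e6, food = 2e6, income = 6e6)
  expect_equal(subsistence_expenditure(hh), 2e6)

  # 100 households with total expenditure = rank: cross-check sort-and-slice
  te <- sample(1:100)
  food <- te / 2
  hh <- make_households(100, te = te, food = food, income = te * 2)
  expect_equal(subsistence_expenditure(hh), oracle_subsistence(te, food))

  # randomized cohorts against the oracle
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(3:60, 1)
    te <- rlnorm(n, 14, 1)
    food <- runif(n, 0.2, 0.7) * te
    hh <- make_households(n, te = te, food = food, income = te)
    expect_equal(subsistence_expenditure(hh), oracle_subsistence(te, food))
  }

  # single household: degenerate window selects it
  hh1 <- make_households(1, te = 3e6, food = 1.2e6, income = 4e6)
  expect_equal(subsistence_expenditure(hh1), 1.2e6)

  expect_error(subsistence_expenditure(make_households(0, 1, 1, 1)),
               class = "fintox_validation_error")
})

test_that("non-subsistence expenditure subtracts and floors at zero", {
  expect_equal(non_subsistence_expenditure(1e6, 4e5), 6e5)
  expect_equal(non_subsistence_expenditure(3e5, 4e5), 0)
  expect_equal(non_subsistence_expenditure(7e5, 0), 7e5)
  expect_error(non_subsistence_expenditure(-1, 0), class = "fintox_validation_error")
})

test_that("CHE thresholds flag weakly-exceeding OOP costs", {
  cfg <- che_config()
  z <- classify_che(0, 1e6, 8e5, cfg)
  expect_false(any(unlist(z)))

  z <- classify_che(110000, 1e6, 8e5, cfg)
  expect_true(z$che_10_te)
  expect_false(z$che_25_te)
  expect_false(z$che_40_nse)
  expect_true(z$any_che)

  # boundary: exactly 25% of TE counts under the weak inequality
  z <- classify_che(0.25 * 1e6, 1e6, 8e5, cfg)
  expect_true(z$che_25_te)
  zs <- classify_che(0.25 * 1e6, 1e6, 8e5, che_config(comparison = "gt"))
  expect_false(zs$che_25_te)

  # exhausted NSE: any positive cost is catastrophic at 40% NSE, zero is not
  z <- classify_che(c(0, 1), 1e6, 0, cfg)
  expect_equal(z$che_40_nse, c(FALSE, TRUE))
})

test_that("poverty lines normalize to annual TZS per adult equivalent", {
  expect_equal(normalize_poverty_line(
    list(amount = 49320, currency = "TZS", period = "per_month")), 591840)
  expect_equal(normalize_poverty_line(
    list(amount = 1.90, currency = "USD", period = "per_person_per_day"),
    rate = 2339), 1.90 * 365 * 2339)
  expect_error(normalize_poverty_line(
    list(amount = 1, currency = "EUR", period = "per_month")),
    class = "fintox_validation_error")
  expect_error(normalize_poverty_line(
    list(amount = 1, currency = "TZS", period = "per_week")),
    class = "fintox_validation_error")
  expect_error(normalize_poverty_line(
    list(amount = 1, currency = "TZS", period = "per_month"), rate = -2),
    class = "fintox_validation_error")
})

test_that("impoverishment compares post-OOP per-adult-equivalent income to the lines", {
  lines <- poverty_lines()
  # comfortably above every line, no cost
  z <- classify_imp(5e8, 2, 0, lines)
  expect_false(any(unlist(z)))
  # exactly 49,319 TZS/month per AE remaining: below the 49,320 national line
  h_a <- 2
  oop <- 1e6
  income <- oop + 49319 * 12 * h_a
  z <- classify_imp(income, h_a, oop, lines)
  expect_true(z$imp_national)
  # costs exceeding income floor remaining income at zero: below all lines
  z <- classify_imp(2e6, 1.5, 3e6, lines)
  expect_true(all(unlist(z)))
  # missing income propagates NA, not an error
  z <- classify_imp(NA_real_, 2, 1e5, lines)
  expect_true(all(is.na(unlist(z))))
})

test_that("toxicity_table is consistent, order-invariant, and join-checked", {
  sched <- tiny_schedule()
  hh <- make_households(6, te = c(2e6, 3e6, 1e6, 5e6, 8e5, 4e6),
                        food = c(9e5, 1e6, 6e5, 1.5e6, 5e5, 1.2e6),
                        income = c(2.5e6, 4e6, 1.2e6, 7e6, 1e6, 5e6))
  enc <- tibble::tibble(patient_id = hh$patient_id, days_general = 0,
                        days_icu = 0, died = FALSE)
  svc <- tibble::tibble(patient_id = hh$patient_id[1], category = "imaging",
                        code_or_modality = "mri", variant = "unknown",
                        laterality = "unknown", quantity = 3)
  costs <- cost_cohort(sched, enc, svc)
  res <- toxicity_table(hh, costs)
  expect_equal(nrow(res), 6)
  expect_equal(res$any_che, Reduce(`|`, res[c("che_10_te", "che_25_te", "che_40_nse")]))
  expect_equal(res$any_imp, Reduce(`|`, res[c("imp_national", "imp_190", "imp_320")]))

  # shuffling households leaves per-patient results unchanged
  perm <- c(4, 1, 6, 2, 5, 3)
  res2 <- toxicity_table(hh[perm, ], costs)
  expect_equal(dplyr::arrange(res2, patient_id), dplyr::arrange(res, patient_id))

  # a household with no cost row is a join error naming the patient
  hh_extra <- rbind(hh, make_households(1, 1e6, 5e5, 1e6))
  hh_extra$patient_id[7] <- "H999"
  expect_error(toxicity_table(hh_extra, costs), "H999", class = "fintox_join_error")
})

test_that("classifier output matches literal brute-force arithmetic on a 100-patient cohort", {
  coh <- generate_cohort(cohort_params(n_patients = 100, seed = 17))
  res <- coh$labels
  se <- attr(res, "subsistence_expenditure")
  for (i in seq_len(100)) {
    hh <- coh$households[i, ]
    te <- hh$annual_total_expenditure
    nse <- max(te - se, 0)
    income <- if (hh$income_missing) NA_real_ else hh$annual_income
    h_a <- 1 + 0.5 * (hh$n_adults - 1) + 0.3 * hh$n_children
    want <- oracle_classify(coh$costs$total_oop[i], te, nse, income, h_a)
    expect_equal(unname(unlist(res[i, c("che_10_te", "che_25_te", "che_40_nse")])),
                 want$che)
    expect_equal(res$any_che[i], want$any_che)
    if (!hh$income_missing) {
      expect_equal(unname(unlist(res[i, c("imp_national", "imp_190", "imp_320")])),
                   want$imp)
      expect_equal(res$any_imp[i], want$any_imp)
    } else {
      expect_true(is.na(res$any_imp[i]))
    }
  }
})

test_that("threshold and poverty-line flags nest as their arithmetic implies", {
  coh <- generate_cohort(cohort_params(n_patients = 150, seed = 23))
  res <- coh$labels
  # 25% of TE implies 10% of TE
  expect_true(all(res$che_10_te[res$che_25_te]))
  # below $1.90/day implies below $3.20/day
  known <- !is.na(res$any_imp)
  expect_true(all(res$imp_320[known & res$imp_190 %in% TRUE]))
  # any-flags are the disjunctions
  expect_equal(res$any_che, Reduce(`|`, res[c("che_10_te", "che_25_te", "che_40_nse")]))
})

test_that("raising OOP never clears a CHE or IMP flag", {
  set.seed(31)
  cfg <- che_config()
  lines <- poverty_lines()
  for (rep in 1:50) {
    te <- rlnorm(1, 14.5, 1)
    nse <- runif(1) * te
    income <- rlnorm(1, 14.5, 1)
    h_a <- adult_equivalents(sample(1:4, 1), sample(0:4, 1))
    oop1 <- runif(1, 0, 2 * te)
    oop2 <- oop1 + runif(1, 0, te)
    che1 <- unlist(classify_che(oop1, te, nse, cfg))
    che2 <- unlist(classify_che(oop2, te, nse, cfg))
    expect_true(all(che2[che1]))
    imp1 <- unlist(classify_imp(income, h_a, oop1, lines))
    imp2 <- unlist(classify_imp(income, h_a, oop2, lines))
    expect_true(all(imp2[imp1]))
  }
})
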