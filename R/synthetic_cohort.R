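#' Parameters for the synthetic trauma cohort generator
#'
#' Defaults emulate the marginal characteristics of the study population:
#' mostly male (83.3%), road-traffic injury dominant (66.7%), largely
#' uninsured (83.3%), median monthly adult-equivalent household income
#' 98,387 TZS with IQR 136,842, median out-of-pocket hospital cost
#' 476,793 TZS with IQR 536,825, dependents brackets 47.4/37.2/15.4% for
#' 0–2/3–5/6+, 80.8% hospitalized, 48.7% requiring surgery, 2.6% in-hospital
#' deaths, and 2/78 households declining to report income.
#'
#' Probability vectors are renormalized to sum exactly to one (the printed
#' percentages carry rounding error); a vector off by more than 1% is
#' rejected.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param prop_male,prop_uninsured,prop_hospitalized,prop_surgery,prop_death,
#'   prop_income_missing Marginal probabilities.
#' @param mechanism_probs Named simplex over `rti`, `fall`, `blunt`, `other`.
#' @param dependents_probs Named simplex over `0-2`, `3-5`, `6+`.
#' @param income_median,income_iqr Monthly adult-equivalent household income
#'   distribution (TZS), modeled lognormal.
#' @param oop_median,oop_iqr Target out-of-pocket cost distribution (TZS),
#'   modeled lognormal.
#' @param education_probs,region_probs,marital_probs,occupation_probs
#'   Demographic simplexes.
#' @param food_share_shape1,food_share_shape2 Beta parameters for the food
#'   share of total expenditure (default mean 0.45).
#' @param target_any_che Optional fraction; when set, service lists are
#'   adjusted so that exactly `round(target_any_che * n_patients)` patients
#'   satisfy at least one catastrophic-expenditure rule.
#' @return A `fintox_cohort_params` list.
#' @export
cohort_params <- function(n_patients = 78, seed = 1,
                          prop_male = 0.833,
                          mechanism_probs = c(rti = 0.667, fall = 0.167,
                                              blunt = 0.103, other = 0.064),
                          prop_uninsured = 0.833,
                          income_median = 98387.1, income_iqr = 136842.1,
                          dependents_probs = c(`0-2` = 0.474, `3-5` = 0.372,
                                               `6+` = 0.154),
                          oop_median = 476792.7, oop_iqr = 536825,
                          prop_hospitalized = 0.808, prop_surgery = 0.487,
                          prop_death = 0.026, prop_income_missing = 2 / 78,
                          education_probs = c(`0-4` = 0.064, `5-10` = 0.564,
                                              `11+` = 0.346, unknown = 0.026),
                          region_probs = c(moshi_rural = 0.615,
                                           moshi_urban = 0.038, other = 0.346),
                          marital_probs = c(single = 0.372, married = 0.474,
                                            other = 0.154),
                          occupation_probs = c(farmer = 0.359,
                                               self_employed = 0.231,
                                               skilled = 0.282, other = 0.128),
                          food_share_shape1 = 9, food_share_shape2 = 11,
                          target_any_che = NULL) {
  if (n_patients < 1) {
    fintox_error("n_patients must be >= 1", "fintox_validation_error")
  }
  fracs <- c(prop_male, prop_uninsured, prop_hospitalized, prop_surgery,
             prop_death, prop_income_missing)
  if (any(fracs < 0 | fracs > 1)) {
    fintox_error("marginal proportions must lie in [0, 1]", "fintox_validation_error")
  }
  if (!is.null(target_any_che) &&
      (target_any_che < 0 || target_any_che > 1)) {
    fintox_error("target_any_che must lie in [0, 1]", "fintox_validation_error")
  }
  norm_simplex <- function(p, what) {
    if (abs(sum(p) - 1) > 0.01) {
      fintox_error(paste0(what, " probabilities must sum to 1 (got ", sum(p), ")"),
                   "fintox_validation_error")
    }
    p / sum(p)
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    prop_male = prop_male,
    mechanism_probs = norm_simplex(mechanism_probs, "mechanism"),
    prop_uninsured = prop_uninsured,
    income_median = income_median, income_iqr = income_iqr,
    dependents_probs = norm_simplex(dependents_probs, "dependents"),
    oop_median = oop_median, oop_iqr = oop_iqr,
    prop_hospitalized = prop_hospitalized, prop_surgery = prop_surgery,
    prop_death = prop_death, prop_income_missing = prop_income_missing,
    education_probs = norm_simplex(education_probs, "education"),
    region_probs = norm_simplex(region_probs, "region"),
    marital_probs = norm_simplex(marital_probs, "marital"),
    occupation_probs = norm_simplex(occupation_probs, "occupation"),
    food_share_shape1 = food_share_shape1,
    food_share_shape2 = food_share_shape2,
    target_any_che = target_any_che
  ), class = "fintox_cohort_params")
}

# sdlog of a lognormal with a given median and interquartile range:
# IQR = 2 * median * sinh(q75 * sdlog), so sdlog = asinh(IQR / 2M) / q75.
lognormal_sdlog <- function(med, iqr) {
  asinh(iqr / (2 * med)) / qnorm(0.75)
}

#' Generate a reproducible synthetic trauma cohort
#'
#' Draws households (composition, income, expenditures), encounters
#' (demographics, injury mechanism, hospitalization, surgery, vital status,
#' length of stay, transfers and delay markers), and an itemized service list
#' per patient, such that the marginal distributions match [cohort_params()].
#' Each patient's service list is assembled from the injury profile and then
#' topped up with consumables so that the costed out-of-pocket total tracks a
#' lognormal draw with the target median. With `target_any_che` set, service
#' lists are further adjusted (consumable top-ups raised for designated
#' catastrophic cases, discretionary services pared back for designated
#' non-cases) so that exactly `round(target * n)` patients satisfy at least
#' one catastrophic-expenditure rule; the resulting ground-truth labels are
#' returned.
#'
#' @param params A [cohort_params()] list.
#' @param schedule Fee schedule used to cost the drawn services; defaults to
#'   the bundled synthetic schedule.
#' @param cfg [che_config()] used for `target_any_che` construction.
#' @return A `fintox_cohort` list with tibbles `households`, `encounters`,
#'   `services`, the `params`, and `labels` (the [toxicity_table()] of the
#'   generated cohort, the generator's ground truth).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_params(n_patients = 20, seed = 42))
#' nrow(coh$households)
generate_cohort <- function(params = cohort_params(),
                            schedule = default_fee_schedule(),
                            cfg = che_config()) {
  stopifnot(inherits(params, "fintox_cohort_params"))
  if (!is.null(params$target_any_che) && all(schedule$unit_cost_tzs == 0)) {
    fintox_error("target_any_che is infeasible with an all-zero fee schedule",
                 "fintox_generation_error")
  }
  n <- params$n_patients
  set.seed(params$seed)
  pid <- sprintf("P%04d", seq_len(n))

  ## --- demographics -------------------------------------------------------
  sex <- ifelse(runif(n) < params$prop_male, "male", "female")
  age <- pmin(95, 18 + round(rlnorm(n, log(14), lognormal_sdlog(14, 20.5))))
  mechanism <- sample(names(params$mechanism_probs), n, replace = TRUE,
                      prob = params$mechanism_probs)
  insurance <- ifelse(runif(n) < params$prop_uninsured, "uninsured", "nhif")
  education <- sample(names(params$education_probs), n, replace = TRUE,
                      prob = params$education_probs)
  region <- sample(names(params$region_probs), n, replace = TRUE,
                   prob = params$region_probs)
  marital <- sample(names(params$marital_probs), n, replace = TRUE,
                    prob = params$marital_probs)
  occupation <- sample(names(params$occupation_probs), n, replace = TRUE,
                       prob = params$occupation_probs)

  ## --- household composition and finances ---------------------------------
  bracket <- sample(names(params$dependents_probs), n, replace = TRUE,
                    prob = params$dependents_probs)
  n_dependents <- vapply(bracket, function(b) {
    switch(b,
           `0-2` = sample(0:2, 1),
           `3-5` = sample(3:5, 1),
           `6+` = 6L + rpois(1, 1.2))
  }, integer(1), USE.NAMES = FALSE)
  n_children <- rbinom(n, n_dependents, 0.7)
  n_adults <- 1L + rpois(n, 0.8) + (n_dependents - n_children)
  h_a <- adult_equivalents(n_adults, n_children)

  income_pae_monthly <- rlnorm(n, log(params$income_median),
                               lognormal_sdlog(params$income_median,
                                               params$income_iqr))
  annual_income <- income_pae_monthly * 12 * h_a
  te <- annual_income * rlnorm(n, log(0.85), 0.25)
  food_share <- rbeta(n, params$food_share_shape1, params$food_share_shape2)
  food <- food_share * te
  income_missing <- runif(n) < params$prop_income_missing

  households <- tibble::tibble(
    patient_id = pid, n_adults = n_adults, n_children = n_children,
    n_dependents = n_dependents, dependents_bracket = bracket,
    annual_income = ifelse(income_missing, NA_real_, annual_income),
    annual_total_expenditure = te, annual_food_expenditure = food,
    income_missing = income_missing
  )

  ## --- encounter ----------------------------------------------------------
  died <- runif(n) < params$prop_death
  hospitalized <- (runif(n) < params$prop_hospitalized) | died
  p_surg <- min(1, params$prop_surgery / max(params$prop_hospitalized, 1e-9))
  surgery <- hospitalized & runif(n) < p_surg
  icu <- hospitalized & (runif(n) < 0.10 | died)
  days_general <- ifelse(hospitalized, 1 + rpois(n, 3), 0)
  days_icu <- ifelse(icu, 1 + rpois(n, 2), 0)
  n_transfers <- rpois(n, 0.4 + 0.8 * surgery + 0.3 * hospitalized)
  surgery_after_transfer <- surgery & n_transfers > 0
  time_to_care <- sample(c("minutes", "hours", "longer"), n, replace = TRUE,
                         prob = c(0.90, 0.08, 0.02))
  delay1_cost_concern <- runif(n) < (0.4 + 0.25 * (insurance == "uninsured"))
  delay1_perceived_severe <- runif(n) < 0.6
  delay1_agency <- runif(n) < 0.3

  encounters <- tibble::tibble(
    patient_id = pid, age = age, sex = sex, education = education,
    region = region, marital_status = marital, occupation = occupation,
    insurance = insurance, mechanism = mechanism,
    hospitalized = hospitalized, surgery = surgery, died = died,
    days_general = days_general, days_icu = days_icu,
    n_transfers = n_transfers,
    surgery_after_transfer = surgery_after_transfer,
    time_to_care = time_to_care,
    delay1_cost_concern = delay1_cost_concern,
    delay1_perceived_severe = delay1_perceived_severe,
    delay1_agency = delay1_agency
  )

  ## --- services -----------------------------------------------------------
  surg_codes <- schedule$code[schedule$category == "procedure_surgical"]
  svc_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- list()
    add <- function(category, code, variant = "unknown", laterality = "unknown",
                    quantity = 1) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        patient_id = pid[i], category = category, code_or_modality = code,
        variant = variant, laterality = laterality, quantity = quantity)
    }
    if (runif(1) < 0.80) {
      if (runif(1) < 0.70) {
        lat <- sample(c("unilateral", "bilateral"), 1, prob = c(0.8, 0.2))
        add("imaging", "xray", variant = lat, laterality = lat)
      } else {
        add("imaging", "xray")  # laterality unrecorded: averaged price
      }
    }
    if (mechanism[i] %in% c("rti", "fall") && runif(1) < 0.30) {
      add("imaging", "ct", variant = sample(c("head", "abdomen"), 1),
          laterality = "na")
    }
    if (runif(1) < 0.25) add("imaging", "uss")   # subtype unrecorded
    if (runif(1) < 0.05) add("imaging", "mri")   # subtype unrecorded
    if (surgery[i] && length(surg_codes) > 0) {
      add("procedure_surgical", sample(surg_codes, 1))
      add("consult_specialist", "consult_surgery")
    }
    if (hospitalized[i]) {
      add("procedure_nonsurgical", "proc_fluids")
      if (runif(1) < 0.30) add("procedure_nonsurgical", "proc_oxygen")
      if (runif(1) < 0.10) add("procedure_nonsurgical", "proc_transfusion")
    }
    if (runif(1) < 0.20) add("consult_therapy", "consult_physio")
    svc_rows[[i]] <- dplyr::bind_rows(rows)
  }
  services <- dplyr::bind_rows(svc_rows)
  if (is.null(services$patient_id)) {
    services <- tibble::tibble(patient_id = character(), category = character(),
                               code_or_modality = character(), variant = character(),
                               laterality = character(), quantity = numeric())
  }

  ## consumable top-up toward the target OOP distribution; targets are
  ## rank-matched to the itemized base cost (costlier injury profiles get the
  ## larger totals), so the costed median tracks the target median
  topup_unit <- schedule$unit_cost_tzs[schedule$code == "cons_saline"]
  target_oop <- rlnorm(n, log(params$oop_median),
                       lognormal_sdlog(params$oop_median, params$oop_iqr))
  base_costs <- cost_cohort(schedule, encounters, services)
  target_oop <- sort(target_oop)[rank(base_costs$total_oop, ties.method = "first")]
  topup_qty <- if (length(topup_unit) == 1 && topup_unit > 0) {
    pmax(0, round((target_oop - base_costs$total_oop) / topup_unit))
  } else {
    rep(0, n)
  }
  topups <- tibble::tibble(
    patient_id = pid, category = "consumable", code_or_modality = "cons_saline",
    variant = "na", laterality = "na", quantity = topup_qty
  )[topup_qty > 0, , drop = FALSE]
  services <- dplyr::bind_rows(services, topups)

  ## --- optional exact-prevalence CHE construction -------------------------
  if (!is.null(params$target_any_che)) {
    adj <- construct_che_target(params, schedule, cfg, households,
                                encounters, services, topup_unit)
    services <- adj$services
    encounters <- adj$encounters
  }

  costs <- cost_cohort(schedule, encounters, services)
  labels <- toxicity_table(households, costs, cfg = cfg)

  structure(list(households = households, encounters = encounters,
                 services = services, costs = costs, labels = labels,
                 params = params),
            class = "fintox_cohort")
}

# Adjust service lists so that exactly round(target * n) patients trip at
# least one CHE rule. Thresholds depend only on household expenditures, never
# on OOP, so they are fixed points of the adjustment.
construct_che_target <- function(params, schedule, cfg, households, encounters,
                                 services, topup_unit) {
  n <- params$n_patients
  k <- round(params$target_any_che * n)
  if (all(schedule$unit_cost_tzs == 0)) {
    fintox_error("target_any_che is infeasible with an all-zero fee schedule",
                 "fintox_generation_error")
  }
  se <- subsistence_expenditure(households)
  te <- households$annual_total_expenditure
  nse <- non_subsistence_expenditure(te, se)
  # smallest OOP that trips any rule; zero marks households where any
  # positive cost is catastrophic (NSE exhausted by subsistence needs)
  m <- ifelse(nse > 0, pmin(0.10 * te, 0.40 * nse), 0)

  em_fee <- schedule$unit_cost_tzs[schedule$code == EM_CONSULT_CODE]
  costs <- cost_cohort(schedule, encounters, services)
  death_cost <- vapply(encounters$died, function(d) compute_death_cost(schedule, d),
                       numeric(1))
  floor_cost <- em_fee + death_cost  # all listed services are discretionary
  feasible_non_che <- floor_cost < m
  if (sum(!feasible_non_che) > k) {
    fintox_error(paste0("target_any_che infeasible: ", sum(!feasible_non_che),
                        " households trip a CHE rule at the minimum billable",
                        " cost but only ", k, " catastrophic cases requested"),
                 "fintox_generation_error")
  }
  propensity <- costs$total_oop / pmax(m, 1)
  propensity[!feasible_non_che] <- Inf
  che_set <- order(propensity, decreasing = TRUE)[seq_len(k)]
  is_che <- seq_len(n) %in% che_set

  pid <- households$patient_id
  if (topup_unit <= 0) topup_unit <- min(schedule$unit_cost_tzs[schedule$unit_cost_tzs > 0])
  for (i in seq_len(n)) {
    oop_i <- costs$total_oop[i]
    if (is_che[i] && oop_i < m[i]) {
      extra <- ceiling((m[i] - oop_i) / topup_unit)
      services <- dplyr::bind_rows(services, tibble::tibble(
        patient_id = pid[i], category = "consumable",
        code_or_modality = "cons_saline", variant = "na", laterality = "na",
        quantity = extra))
    } else if (!is_che[i] && oop_i >= m[i]) {
      # pare back this patient's services, most expensive first, until the
      # total drops below the smallest threshold; then stay, day by day
      repeat {
        if (oop_i < m[i]) break
        idx <- which(services$patient_id == pid[i])
        if (length(idx) == 0) break
        line_costs <- vapply(idx, function(j) resolve_item_cost(schedule, services[j, ]),
                             numeric(1))
        j <- which.max(line_costs)
        oop_i <- oop_i - line_costs[j]
        services <- services[-idx[j], , drop = FALSE]
      }
      enc_row <- match(pid[i], encounters$patient_id)
      while (oop_i >= m[i] &&
             (encounters$days_general[enc_row] > 0 || encounters$days_icu[enc_row] > 0)) {
        if (encounters$days_icu[enc_row] > 0) {
          encounters$days_icu[enc_row] <- encounters$days_icu[enc_row] - 1L
          oop_i <- oop_i - ward_rate(schedule, "icu")
        } else {
          encounters$days_general[enc_row] <- encounters$days_general[enc_row] - 1L
          oop_i <- oop_i - ward_rate(schedule, "general")
        }
      }
      if (oop_i >= m[i]) {
        fintox_error(paste0("could not construct a non-catastrophic cost for ",
                            pid[i]), "fintox_generation_error")
      }
    }
  }
  list(services = services, encounters = encounters)
}

#' Write a synthetic cohort to disk as delimited text
#'
#' Emits `households.csv`, `encounters.csv`, and `services.csv` in the exact
#' dialects the pipeline reads, plus a `manifest.json` recording the
#' generator parameters (including the seed).
#'
#' @param cohort A `fintox_cohort` from [generate_cohort()].
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fintox_cohort"))
  if (nrow(cohort$households) == 0) {
    fintox_error("refusing to write an empty cohort", "fintox_validation_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(households = file.path(dir, "households.csv"),
             encounters = file.path(dir, "encounters.csv"),
             services = file.path(dir, "services.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(cohort$households, paths[["households"]], progress = FALSE)
  readr::write_csv(cohort$encounters, paths[["encounters"]], progress = FALSE)
  readr::write_csv(cohort$services, paths[["services"]], progress = FALSE)
  manifest <- unclass(cohort$params)
  manifest$generated_n <- nrow(cohort$households)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir Directory containing the three cohort CSVs.
#' @return A list with tibbles `households`, `encounters`, `services`.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("households.csv", "encounters.csv", "services.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    fintox_error(paste0("cohort fixture incomplete, missing: ",
                        paste(basename(missing), collapse = ", ")),
                 "fintox_schema_error")
  }
  households <- readr::read_csv(need[1], col_types = readr::cols(
    patient_id = readr::col_character(), dependents_bracket = readr::col_character(),
    income_missing = readr::col_logical(), .default = readr::col_double()),
    progress = FALSE)
  encounters <- readr::read_csv(need[2], col_types = readr::cols(
    age = readr::col_double(), days_general = readr::col_double(),
    days_icu = readr::col_double(), n_transfers = readr::col_double(),
    hospitalized = readr::col_logical(), surgery = readr::col_logical(),
    died = readr::col_logical(), surgery_after_transfer = readr::col_logical(),
    delay1_cost_concern = readr::col_logical(),
    delay1_perceived_severe = readr::col_logical(),
    delay1_agency = readr::col_logical(), .default = readr::col_character()),
    progress = FALSE)
  services <- readr::read_csv(need[3], col_types = readr::cols(
    quantity = readr::col_double(), .default = readr::col_character()),
    progress = FALSE)
  list(households = households, encounters = encounters, services = services)
}
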