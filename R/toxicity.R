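#' OECD-modified adult equivalents of a household
#'
#' Weights the first adult 1, each further adult 0.5, and each child
#' (under 14) 0.3.
#'
#' @param n_adults Number of adults (>= 1); vectorized.
#' @param n_children Number of children (>= 0); vectorized.
#' @return Adult-equivalent household size(s).
#' @export
#' @examples
#' adult_equivalents(2, 2) # 2.1
adult_equivalents <- function(n_adults, n_children = 0) {
  if (anyNA(n_adults) || any(n_adults < 1)) {
    fintox_error("households must contain at least one adult", "fintox_validation_error")
  }
  if (anyNA(n_children) || any(n_children < 0)) {
    fintox_error("n_children must be non-negative", "fintox_validation_error")
  }
  1 + 0.5 * (n_adults - 1) + 0.3 * n_children
}

#' Subsistence expenditure of a cohort
#'
#' Estimates the basic-needs spending floor as the mean annual food
#' expenditure of the households lying in a central consumption band: the
#' cohort is ranked by annual total household expenditure, each household is
#' assigned the percentile rank `100 * (rank - 0.5) / n` (ties broken by
#' stable input order), and households whose percentile falls in the closed
#' window (default 45th–55th) are averaged. If no household falls inside the
#' window (possible for very small cohorts) the household nearest the median
#' percentile is used, preferring the lower rank on ties.
#'
#' @param households Tibble with `annual_total_expenditure` and
#'   `annual_food_expenditure` (TZS).
#' @param window Closed percentile window, default `c(45, 55)`.
#' @return Subsistence expenditure in TZS per household per year.
#' @export
subsistence_expenditure <- function(households, window = c(45, 55)) {
  te <- households$annual_total_expenditure
  food <- households$annual_food_expenditure
  keep <- !is.na(te) & !is.na(food)
  te <- te[keep]
  food <- food[keep]
  n <- length(te)
  if (n == 0) {
    fintox_error("no households with non-missing expenditure", "fintox_validation_error")
  }
  r <- integer(n)
  r[order(te)] <- seq_len(n)   # order() is stable: ties keep input order
  pct <- 100 * (r - 0.5) / n
  inside <- pct >= window[1] & pct <= window[2]
  if (!any(inside)) {
    inside <- seq_len(n) == which.min(abs(pct - mean(window)))
  }
  mean(food[inside])
}

#' Non-subsistence expenditure
#'
#' Total expenditure minus subsistence expenditure, floored at zero for
#' households spending less than the subsistence floor.
#'
#' @param te,se Annual total and subsistence expenditure (TZS); vectorized.
#' @return Non-subsistence expenditure (TZS).
#' @export
non_subsistence_expenditure <- function(te, se) {
  if (any(te < 0, na.rm = TRUE) || any(se < 0, na.rm = TRUE)) {
    fintox_error("expenditures must be non-negative", "fintox_validation_error")
  }
  pmax(te - se, 0)
}

#' Catastrophic-expenditure threshold configuration
#'
#' The default thresholds are OOP >= 10% of total household expenditure (TE),
#' OOP >= 25% of TE, and OOP >= 40% of non-subsistence expenditure (NSE).
#' `comparison = "ge"` uses a weak inequality (a cost exactly at the
#' threshold counts as catastrophic); `"gt"` is strict.
#'
#' @param fractions Numeric threshold fractions in (0, 1).
#' @param bases Character vector, `"te"` or `"nse"`, one per fraction.
#' @param comparison `"ge"` (default) or `"gt"`.
#' @return A `fintox_che_config` list.
#' @export
che_config <- function(fractions = c(0.10, 0.25, 0.40),
                       bases = c("te", "te", "nse"),
                       comparison = c("ge", "gt")) {
  comparison <- match.arg(comparison)
  if (length(fractions) != length(bases)) {
    fintox_error("fractions and bases must have equal length", "fintox_validation_error")
  }
  if (any(fractions <= 0) || any(fractions >= 1)) {
    fintox_error("threshold fractions must lie strictly between 0 and 1",
                 "fintox_validation_error")
  }
  if (!all(bases %in% c("te", "nse"))) {
    fintox_error("bases must be 'te' or 'nse'", "fintox_validation_error")
  }
  labels <- paste0("che_", round(100 * fractions), "_", bases)
  structure(list(fractions = fractions, bases = bases, labels = labels,
                 comparison = comparison),
            class = "fintox_che_config")
}

#' Classify catastrophic health expenditure
#'
#' Flags a patient for each configured threshold when out-of-pocket cost
#' meets the threshold fraction of its base (TE or NSE); `any_che` is the
#' disjunction — exceeding any one threshold marks the patient as having
#' experienced a catastrophic health expense. When a household's NSE is zero
#' (total spending at or below the subsistence floor) the 40%-of-NSE rule
#' fires for any positive OOP cost, but not for a zero-cost encounter.
#'
#' @param oop,te,nse Vectors of OOP cost, total expenditure, and
#'   non-subsistence expenditure (TZS), recycled to a common length.
#' @param cfg A [che_config()].
#' @return Tibble with one logical column per threshold plus `any_che`.
#' @export
classify_che <- function(oop, te, nse, cfg = che_config()) {
  n <- max(length(oop), length(te), length(nse))
  oop <- rep_len(oop, n); te <- rep_len(te, n); nse <- rep_len(nse, n)
  if (any(oop < 0, na.rm = TRUE)) {
    fintox_error("OOP costs must be non-negative", "fintox_validation_error")
  }
  cmp <- if (cfg$comparison == "ge") `>=` else `>`
  out <- tibble::tibble(.rows = n)
  for (i in seq_along(cfg$fractions)) {
    base <- if (cfg$bases[i] == "te") te else nse
    flag <- cmp(oop, cfg$fractions[i] * base)
    zero_base <- !is.na(base) & base == 0
    flag[zero_base] <- oop[zero_base] > 0
    out[[cfg$labels[i]]] <- flag
  }
  out$any_che <- Reduce(`|`, out[cfg$labels])
  out
}

#' Poverty lines
#'
#' The default set: the Tanzanian national basic-needs poverty line of
#' 49,320 TZS per month, and the international lines of $1.90 and $3.20 per
#' person per day.
#'
#' @param label,amount,currency,period Vectors describing each line;
#'   `currency` is `"TZS"` or `"USD"`, `period` is `"per_month"` or
#'   `"per_person_per_day"`.
#' @return Tibble of poverty lines.
#' @export
poverty_lines <- function(label = c("imp_national", "imp_190", "imp_320"),
                          amount = c(49320, 1.90, 3.20),
                          currency = c("TZS", "USD", "USD"),
                          period = c("per_month", "per_person_per_day",
                                     "per_person_per_day")) {
  if (any(amount <= 0)) {
    fintox_error("poverty-line amounts must be positive", "fintox_validation_error")
  }
  tibble::tibble(label = label, amount = amount, currency = currency, period = period)
}

#' Normalize a poverty line to annual TZS per adult equivalent
#'
#' Monthly lines are multiplied by 12, per-day lines by 365, and USD lines by
#' the TZS/USD conversion rate.
#'
#' @param line One-row tibble or list with `amount`, `currency`, `period`.
#' @param rate TZS per USD.
#' @return Annual amount in TZS.
#' @export
#' @examples
#' normalize_poverty_line(list(amount = 49320, currency = "TZS",
#'                             period = "per_month")) # 591840
normalize_poverty_line <- function(line, rate = TZS_PER_USD) {
  line <- as.list(line)
  if (!is.numeric(rate) || rate <= 0) {
    fintox_error("conversion rate must be positive", "fintox_validation_error")
  }
  amount <- line$amount
  amount <- switch(line$currency,
    TZS = amount,
    USD = amount * rate,
    fintox_error(paste0("unknown currency: ", line$currency), "fintox_validation_error")
  )
  switch(line$period,
    per_month = amount * 12,
    per_person_per_day = amount * 365,
    fintox_error(paste0("unknown period: ", line$period), "fintox_validation_error")
  )
}

#' Classify impoverishment by out-of-pocket spending
#'
#' A patient is impoverished at a poverty line when household income remaining
#' after OOP costs, scaled to adult equivalents, falls strictly below the
#' annualized line. In the default `"absolute"` mode the comparison is made
#' regardless of the household's pre-cost position; `"newly_poor"`
#' additionally requires the household to have been at or above the line
#' before the expense. Households with missing income receive `NA` flags.
#'
#' @param annual_income Annual household income (TZS); `NA` when missing.
#' @param h_a Adult-equivalent household sizes.
#' @param oop OOP costs (TZS).
#' @param lines A [poverty_lines()] tibble.
#' @param rate TZS per USD for the USD lines.
#' @param mode `"absolute"` (default) or `"newly_poor"`.
#' @return Tibble with one logical column per line plus `any_imp`.
#' @export
classify_imp <- function(annual_income, h_a, oop, lines = poverty_lines(),
                         rate = TZS_PER_USD, mode = c("absolute", "newly_poor")) {
  mode <- match.arg(mode)
  n <- max(length(annual_income), length(h_a), length(oop))
  annual_income <- rep_len(annual_income, n)
  h_a <- rep_len(h_a, n)
  oop <- rep_len(oop, n)
  if (any(oop < 0, na.rm = TRUE)) {
    fintox_error("OOP costs must be non-negative", "fintox_validation_error")
  }
  remaining_pae <- pmax(annual_income - oop, 0) / h_a
  pre_pae <- annual_income / h_a
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(lines))) {
    z <- normalize_poverty_line(lines[i, ], rate)
    flag <- remaining_pae < z
    if (mode == "newly_poor") flag <- flag & pre_pae >= z
    out[[lines$label[i]]] <- flag
  }
  out$any_imp <- Reduce(`|`, out[lines$label])
  out
}

#' Per-patient financial-toxicity classification of a cohort
#'
#' Computes subsistence expenditure once from the full cohort, then applies
#' the catastrophic-expenditure and impoverishment rules to every patient.
#'
#' @param households Tibble with `patient_id`, `n_adults`, `n_children`,
#'   `annual_income`, `annual_total_expenditure`, `annual_food_expenditure`,
#'   and `income_missing`.
#' @param costs Cost table from [cost_cohort()] (needs `patient_id`,
#'   `total_oop`).
#' @param cfg A [che_config()].
#' @param lines A [poverty_lines()] tibble.
#' @param rate TZS per USD.
#' @param imp_mode Passed to [classify_imp()].
#' @param window Subsistence percentile window.
#' @return Tibble with one row per patient: `oop`, `te`, `nse`, `h_a`, the
#'   CHE and IMP flags, `any_che`, `any_imp`, and `income_missing`. The
#'   cohort subsistence expenditure is attached as attribute
#'   `subsistence_expenditure`.
#' @export
toxicity_table <- function(households, costs, cfg = che_config(),
                           lines = poverty_lines(), rate = TZS_PER_USD,
                           imp_mode = "absolute", window = c(45, 55)) {
  unmatched <- setdiff(households$patient_id, costs$patient_id)
  if (length(unmatched) > 0) {
    fintox_error(paste0("no cost row for patient_id(s): ",
                        paste(head(unmatched, 5), collapse = ", ")),
                 "fintox_join_error")
  }
  joined <- dplyr::left_join(households,
                             costs[, c("patient_id", "total_oop")],
                             by = "patient_id")
  se <- subsistence_expenditure(households, window = window)
  te <- joined$annual_total_expenditure
  nse <- non_subsistence_expenditure(te, se)
  h_a <- adult_equivalents(joined$n_adults, joined$n_children)
  income <- ifelse(joined$income_missing, NA_real_, joined$annual_income)
  che <- classify_che(joined$total_oop, te, nse, cfg)
  imp <- classify_imp(income, h_a, joined$total_oop, lines, rate, imp_mode)
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = joined$patient_id, oop = joined$total_oop,
                   te = te, nse = nse, h_a = h_a,
                   income_missing = joined$income_missing),
    che, imp
  )
  attr(out, "subsistence_expenditure") <- se
  out
}
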