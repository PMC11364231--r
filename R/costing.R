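#' Fee-schedule categories recognised by the costing engine
#'
#' @format Character vector of the nine billable item categories.
#' @export
FEE_CATEGORIES <- c(
  "consult_specialist", "consult_generalist", "consult_therapy",
  "procedure_nonsurgical", "procedure_surgical", "imaging",
  "admission_day", "consumable", "death_expense"
)

# Codes that must be present for a death to be costed: a death certificate,
# transport from the ward to the morgue, and a body bag.
DEATH_CODES <- c("death_certificate", "morgue_transport", "body_bag")

# Code of the mandatory emergency-physician consultation: every encounter is
# billed this specialist fee regardless of the service list.
EM_CONSULT_CODE <- "consult_emergency"

UNKNOWN_TOKEN <- "unknown"

is_unknown <- function(x) is.na(x) | x == UNKNOWN_TOKEN | x == ""

#' Load and validate an itemized fee schedule
#'
#' Reads a comma-delimited fee schedule with header
#' `code,category,unit_cost_tzs,modality,variant,ward` and validates it:
#' unit costs must be non-negative, codes unique, categories drawn from
#' [FEE_CATEGORIES], imaging items must carry a modality and admission-day
#' items a ward (`general` or `icu`).
#'
#' @param path Path to a CSV file.
#' @return A tibble of fee items (class `fintox_fee_schedule`).
#' @export
#' @examples
#' sched <- load_fee_schedule(fintox_example("fee_schedule_synthetic.csv"))
#' head(sched)
load_fee_schedule <- function(path) {
  if (!file.exists(path)) {
    fintox_error(paste0("fee schedule file not found: ", path),
                 "fintox_schema_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("code", "category", "unit_cost_tzs", "modality", "variant", "ward")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    fintox_error(paste0("fee schedule is missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 "fintox_schema_error")
  }
  raw$unit_cost_tzs <- suppressWarnings(as.numeric(raw$unit_cost_tzs))
  validate_fee_schedule(raw)
}

#' @rdname load_fee_schedule
#' @param items A data frame with the fee-schedule columns, built in code.
#' @export
as_fee_schedule <- function(items) {
  items <- tibble::as_tibble(items)
  for (col in c("modality", "variant", "ward")) {
    if (!col %in% names(items)) items[[col]] <- NA_character_
  }
  validate_fee_schedule(items)
}

validate_fee_schedule <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyNA(df$unit_cost_tzs)) {
    fintox_error("fee schedule has missing or non-numeric unit_cost_tzs values",
                 "fintox_validation_error")
  }
  if (any(df$unit_cost_tzs < 0)) {
    bad <- df$code[df$unit_cost_tzs < 0]
    fintox_error(paste0("negative unit_cost_tzs for item(s): ",
                        paste(bad, collapse = ", ")),
                 "fintox_validation_error")
  }
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup) > 0) {
    fintox_error(paste0("duplicate fee-schedule code(s): ",
                        paste(dup, collapse = ", ")),
                 "fintox_validation_error")
  }
  bad_cat <- setdiff(unique(df$category), FEE_CATEGORIES)
  if (length(bad_cat) > 0) {
    fintox_error(paste0("unknown fee category: ", paste(bad_cat, collapse = ", ")),
                 "fintox_validation_error")
  }
  img <- df$category == "imaging"
  if (any(img & is_unknown(df$modality))) {
    fintox_error("imaging items must carry a modality", "fintox_validation_error")
  }
  adm <- df$category == "admission_day"
  if (any(adm & !df$ward %in% c("general", "icu"))) {
    fintox_error("admission_day items must carry ward 'general' or 'icu'",
                 "fintox_validation_error")
  }
  class(df) <- c("fintox_fee_schedule", class(df))
  df
}

#' Path to a file bundled with the package
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
fintox_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "fintox"))
  } else {
    system.file("extdata", file, package = "fintox", mustWork = TRUE)
  }
}

#' The bundled synthetic default fee schedule
#'
#' Unit prices in this schedule are synthetic placeholders with plausible
#' relative magnitudes for a Tanzanian zonal referral hospital; they are not a
#' real price list. Supply an institution's own schedule via
#' [load_fee_schedule()] for real analyses.
#'
#' @return A validated fee schedule tibble.
#' @export
default_fee_schedule <- function() {
  load_fee_schedule(fintox_example("fee_schedule_synthetic.csv"))
}

#' Resolve the cost of one recorded service against a fee schedule
#'
#' Applies the study's substitution rules. A service that names a schedule
#' `code` directly is priced at that item's unit cost. An imaging service that
#' names only a modality (x-ray, CT, MRI, ultrasound) is matched to all
#' schedule items of that modality, narrowed by its `variant` (subtype or
#' laterality token) when known; whenever the subtype or laterality remains
#' unknown, the arithmetic mean of the remaining candidate items is
#' substituted — so an unknown-subtype MRI costs the average of all MRI items,
#' and an unknown-laterality scan the average of the unilateral and bilateral
#' prices. The resolved unit cost is multiplied by `quantity`.
#'
#' @param schedule A fee schedule from [load_fee_schedule()].
#' @param svc A list or one-row data frame with fields `category`,
#'   `code_or_modality`, `variant`, `laterality`, `quantity`. Unknown variant
#'   or laterality is the literal token `"unknown"` (or `NA`).
#' @return Cost in TZS (length-1 numeric).
#' @export
#' @examples
#' sched <- default_fee_schedule()
#' resolve_item_cost(sched, list(category = "imaging", code_or_modality = "mri",
#'                               variant = "unknown", laterality = "unknown",
#'                               quantity = 1))
resolve_item_cost <- function(schedule, svc) {
  svc <- as.list(svc)
  qty <- if (is.null(svc$quantity) || is.na(svc$quantity)) 1L else as.numeric(svc$quantity)
  if (qty < 1) {
    fintox_error("service quantity must be >= 1", "fintox_validation_error")
  }
  unit <- resolve_unit_cost(schedule, svc)
  unit * qty
}

resolve_unit_cost <- function(schedule, svc) {
  key <- svc$code_or_modality
  hit <- schedule[schedule$code == key & !is.na(schedule$code), , drop = FALSE]
  if (nrow(hit) == 1) {
    return(hit$unit_cost_tzs)
  }
  # No direct code: only imaging may be matched by modality with substitution.
  cand <- schedule[schedule$category == svc$category &
                     !is_unknown(schedule$modality) &
                     schedule$modality == key, , drop = FALSE]
  if (nrow(cand) == 0) {
    fintox_error(paste0("unresolvable service item: category=", svc$category,
                        " code_or_modality=", key),
                 "fintox_unresolvable_item_error")
  }
  var_known <- !is_unknown(svc$variant %||% NA_character_)
  lat_known <- !is_unknown(svc$laterality %||% NA_character_)
  if (var_known) {
    cand <- cand[!is_unknown(cand$variant) & cand$variant == svc$variant, , drop = FALSE]
  } else if (lat_known) {
    lat_cand <- cand[!is_unknown(cand$variant) & cand$variant == svc$laterality, , drop = FALSE]
    # Schedules that do not price this modality by laterality fall back to the
    # full candidate set (subtype still unknown).
    if (nrow(lat_cand) > 0) cand <- lat_cand
  }
  if (nrow(cand) == 0) {
    fintox_error(paste0("no fee item matches variant '", svc$variant,
                        "' for modality ", key),
                 "fintox_unresolvable_item_error")
  }
  if (nrow(cand) == 1) {
    return(cand$unit_cost_tzs)
  }
  if (var_known && lat_known) {
    fintox_error(paste0("ambiguous fully-specified service for modality ", key),
                 "fintox_unresolvable_item_error")
  }
  mean(cand$unit_cost_tzs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cost of the hospital stay
#'
#' Days on the general ward are billed at the basic shared-ward rate (the
#' cheapest `general` admission-day item) and ICU days at the ICU daily rate.
#'
#' @param schedule A fee schedule.
#' @param days_general,days_icu Non-negative integer day counts.
#' @return Stay cost in TZS.
#' @export
compute_stay_cost <- function(schedule, days_general, days_icu) {
  if (any(c(days_general, days_icu) < 0) || anyNA(c(days_general, days_icu))) {
    fintox_error("length of stay must be non-negative", "fintox_validation_error")
  }
  if (days_general + days_icu == 0) {
    return(0)
  }
  days_general * ward_rate(schedule, "general") +
    days_icu * ward_rate(schedule, "icu")
}

ward_rate <- function(schedule, ward) {
  items <- schedule[schedule$category == "admission_day" &
                      schedule$ward == ward & !is.na(schedule$ward), , drop = FALSE]
  if (nrow(items) == 0) {
    fintox_error(paste0("fee schedule has no admission_day rate for ward: ", ward),
                 "fintox_unresolvable_item_error")
  }
  min(items$unit_cost_tzs)
}

#' Death-related expenses
#'
#' For in-hospital deaths, the death certificate, transport from the wards to
#' the morgue, and a body bag are billed; zero otherwise.
#'
#' @param schedule A fee schedule.
#' @param died Logical flag.
#' @return Death expense in TZS.
#' @export
compute_death_cost <- function(schedule, died) {
  if (is.na(died) || !died) {
    return(0)
  }
  death_items <- schedule[schedule$category == "death_expense", , drop = FALSE]
  missing <- setdiff(DEATH_CODES, death_items$code)
  if (length(missing) > 0) {
    fintox_error(paste0("fee schedule is missing death expense item(s): ",
                        paste(missing, collapse = ", ")),
                 "fintox_unresolvable_item_error")
  }
  sum(death_items$unit_cost_tzs[death_items$code %in% DEATH_CODES])
}

#' Itemized out-of-pocket cost breakdown for one encounter
#'
#' Builds the six-component OOP breakdown: consultations (always including one
#' emergency-physician specialist fee — every patient saw the emergency
#' physician), procedures (surgical billed as the procedural fee only),
#' imaging, stay, consumables, and death expenses. Citizen rates are assumed
#' throughout; costs are pre-insurance-reimbursement.
#'
#' @param schedule A fee schedule.
#' @param encounter A list or one-row data frame with `days_general`,
#'   `days_icu`, and `died`.
#' @param services A data frame of the encounter's service records with
#'   columns `category`, `code_or_modality`, `variant`, `laterality`,
#'   `quantity` (may have zero rows). The mandatory emergency consultation
#'   must not be listed; it is added automatically.
#' @return One-row tibble: `consultations`, `procedures`, `imaging`, `stay`,
#'   `consumables`, `death`, `total_oop` (all TZS).
#' @export
compute_oop <- function(schedule, encounter, services = NULL) {
  encounter <- as.list(encounter)
  if (is.null(services)) {
    services <- tibble::tibble(category = character(), code_or_modality = character(),
                               variant = character(), laterality = character(),
                               quantity = numeric())
  }
  em_fee_items <- schedule[schedule$code == EM_CONSULT_CODE, , drop = FALSE]
  if (nrow(em_fee_items) != 1) {
    fintox_error(paste0("fee schedule must contain the emergency-physician consult item '",
                        EM_CONSULT_CODE, "'"),
                 "fintox_unresolvable_item_error")
  }
  comp <- c(consultations = em_fee_items$unit_cost_tzs, procedures = 0,
            imaging = 0, stay = 0, consumables = 0, death = 0)
  if (nrow(services) > 0) {
    for (i in seq_len(nrow(services))) {
      svc <- services[i, , drop = FALSE]
      cost <- tryCatch(
        resolve_item_cost(schedule, svc),
        fintox_error = function(e) {
          fintox_error(paste0("service row ", i,
                              if (!is.null(svc$patient_id)) paste0(" (patient ", svc$patient_id, ")"),
                              ": ", conditionMessage(e)),
                       class(e)[[1]])
        }
      )
      slot <- switch(svc$category,
        consult_specialist = , consult_generalist = , consult_therapy = "consultations",
        procedure_nonsurgical = , procedure_surgical = "procedures",
        imaging = "imaging",
        consumable = "consumables",
        death_expense = "death",
        fintox_error(paste0("service category not billable as a line item: ",
                            svc$category),
                     "fintox_validation_error")
      )
      comp[slot] <- comp[slot] + cost
    }
  }
  comp["stay"] <- comp["stay"] +
    compute_stay_cost(schedule, encounter$days_general %||% 0, encounter$days_icu %||% 0)
  comp["death"] <- comp["death"] +
    compute_death_cost(schedule, isTRUE(encounter$died))
  tibble::tibble(
    consultations = comp[["consultations"]], procedures = comp[["procedures"]],
    imaging = comp[["imaging"]], stay = comp[["stay"]],
    consumables = comp[["consumables"]], death = comp[["death"]],
    total_oop = sum(comp)
  )
}

#' Cost a whole cohort of encounters
#'
#' @param schedule A fee schedule.
#' @param encounters Tibble with `patient_id`, `days_general`, `days_icu`,
#'   `died`.
#' @param services Long-format service table with `patient_id` plus the
#'   service-record columns (see [compute_oop()]).
#' @return Tibble with one [compute_oop()] breakdown row per patient, keyed by
#'   `patient_id`.
#' @export
cost_cohort <- function(schedule, encounters, services) {
  stray <- setdiff(unique(services$patient_id), encounters$patient_id)
  if (length(stray) > 0) {
    fintox_error(paste0("service rows reference unknown patient_id(s): ",
                        paste(head(stray, 5), collapse = ", ")),
                 "fintox_join_error")
  }
  n <- nrow(encounters)
  em_fee_items <- schedule[schedule$code == EM_CONSULT_CODE, , drop = FALSE]
  if (nrow(em_fee_items) != 1) {
    fintox_error(paste0("fee schedule must contain the emergency-physician consult item '",
                        EM_CONSULT_CODE, "'"),
                 "fintox_unresolvable_item_error")
  }
  comp <- matrix(0, nrow = n, ncol = 6,
                 dimnames = list(NULL, c("consultations", "procedures", "imaging",
                                         "stay", "consumables", "death")))
  comp[, "consultations"] <- em_fee_items$unit_cost_tzs

  if (nrow(services) > 0) {
    qty <- ifelse(is.na(services$quantity), 1, services$quantity)
    if (any(qty < 1)) {
      fintox_error("service quantity must be >= 1", "fintox_validation_error")
    }
    # resolve each distinct (category, item, variant, laterality) once
    key <- paste(services$category, services$code_or_modality,
                 services$variant, services$laterality, sep = "\r")
    first <- !duplicated(key)
    unit_by_key <- vapply(which(first), function(j) {
      tryCatch(resolve_unit_cost(schedule, as.list(services[j, ])),
               fintox_error = function(e) {
                 fintox_error(paste0("service row ", j, " (patient ",
                                     services$patient_id[j], "): ",
                                     conditionMessage(e)),
                              class(e)[[1]])
               })
    }, numeric(1))
    line_cost <- unit_by_key[match(key, key[first])] * qty
    slot <- c(consult_specialist = "consultations",
              consult_generalist = "consultations",
              consult_therapy = "consultations",
              procedure_nonsurgical = "procedures",
              procedure_surgical = "procedures",
              imaging = "imaging", consumable = "consumables",
              death_expense = "death")[services$category]
    if (anyNA(slot)) {
      fintox_error(paste0("service category not billable as a line item: ",
                          services$category[which(is.na(slot))[1]]),
                   "fintox_validation_error")
    }
    pidx <- match(services$patient_id, encounters$patient_id)
    sidx <- match(slot, colnames(comp))
    for (k in seq_along(line_cost)) {
      comp[pidx[k], sidx[k]] <- comp[pidx[k], sidx[k]] + line_cost[k]
    }
  }

  dg <- encounters$days_general %||% rep(0, n)
  di <- encounters$days_icu %||% rep(0, n)
  if (any(c(dg, di) < 0, na.rm = TRUE) || anyNA(c(dg, di))) {
    fintox_error("length of stay must be non-negative", "fintox_validation_error")
  }
  if (any(dg > 0)) comp[, "stay"] <- comp[, "stay"] + dg * ward_rate(schedule, "general")
  if (any(di > 0)) comp[, "stay"] <- comp[, "stay"] + di * ward_rate(schedule, "icu")
  died <- encounters$died %||% rep(FALSE, n)
  if (any(died, na.rm = TRUE)) {
    dcost <- compute_death_cost(schedule, TRUE)
    comp[, "death"] <- comp[, "death"] + ifelse(died %in% TRUE, dcost, 0)
  }
  tibble::tibble(
    patient_id = encounters$patient_id,
    consultations = comp[, "consultations"], procedures = comp[, "procedures"],
    imaging = comp[, "imaging"], stay = comp[, "stay"],
    consumables = comp[, "consumables"], death = comp[, "death"],
    total_oop = rowSums(comp)
  )
}

#' Convert Tanzanian shillings to US dollars
#'
#' @param amount_tzs Amount(s) in TZS.
#' @param rate TZS per 1 USD; the study rate of 2,339 is the default.
#' @param round_to `"none"` (exact), `"integer"` (nearest whole dollar, used
#'   for headline figures), or `"cents"`.
#' @return Amount(s) in USD.
#' @export
#' @examples
#' convert_tzs_to_usd(476792.7, round_to = "integer") # 204
convert_tzs_to_usd <- function(amount_tzs, rate = TZS_PER_USD,
                               round_to = c("none", "integer", "cents")) {
  round_to <- match.arg(round_to)
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate <= 0) {
    fintox_error("conversion rate must be a positive number (TZS per USD)",
                 "fintox_validation_error")
  }
  usd <- amount_tzs / rate
  switch(round_to, none = usd, integer = round(usd), cents = round(usd, 2))
}
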