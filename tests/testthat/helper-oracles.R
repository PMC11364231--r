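# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles: flat
# enumeration for costing, literal threshold arithmetic for the classifiers,
# sort-and-slice for the subsistence window.

# a small schedule built in code, used by many tests
tiny_schedule <- function() {
  as_fee_schedule(tibble::tibble(
    code = c("consult_emergency", "consult_surgery", "proc_fluids",
             "surg_fix", "img_xr_uni", "img_xr_bil", "img_mri_a", "img_mri_b",
             "bed_gen", "bed_icu", "cons_saline",
             "death_certificate", "morgue_transport", "body_bag"),
    category = c("consult_specialist", "consult_specialist",
                 "procedure_nonsurgical", "procedure_surgical",
                 "imaging", "imaging", "imaging", "imaging",
                 "admission_day", "admission_day", "consumable",
                 "death_expense", "death_expense", "death_expense"),
    unit_cost_tzs = c(20000, 25000, 12000, 450000, 50000, 80000,
                      100000, 300000, 10000, 50000, 6000, 5000, 3000, 2000),
    modality = c(NA, NA, NA, NA, "xray", "xray", "mri", "mri",
                 NA, NA, NA, NA, NA, NA),
    variant = c(NA, NA, NA, NA, "unilateral", "bilateral", "a", "b",
                NA, NA, NA, NA, NA, NA),
    ward = c(NA, NA, NA, NA, NA, NA, NA, NA, "general", "icu",
             NA, NA, NA, NA)
  ))
}

# flat enumeration: resolve every line item independently, multiply by
# quantity, add the mandatory EM fee, stay, and death items
oracle_oop_total <- function(schedule, encounter, services) {
  total <- schedule$unit_cost_tzs[schedule$code == "consult_emergency"]
  if (!is.null(services) && nrow(services) > 0) {
    for (i in seq_len(nrow(services))) {
      svc <- as.list(services[i, ])
      qty <- if (is.na(svc$quantity)) 1 else svc$quantity
      hit <- schedule$unit_cost_tzs[schedule$code == svc$code_or_modality]
      if (length(hit) == 1) {
        unit <- hit
      } else {
        cand <- schedule[schedule$category == svc$category &
                           schedule$modality %in% svc$code_or_modality, ]
        if (!svc$variant %in% c(NA, "unknown", "")) {
          cand <- cand[cand$variant %in% svc$variant, ]
        } else if (!svc$laterality %in% c(NA, "unknown", "")) {
          lat <- cand[cand$variant %in% svc$laterality, ]
          if (nrow(lat) > 0) cand <- lat
        }
        unit <- mean(cand$unit_cost_tzs)
      }
      total <- total + unit * qty
    }
  }
  gen <- schedule$unit_cost_tzs[schedule$category == "admission_day" &
                                  schedule$ward %in% "general"]
  icu <- schedule$unit_cost_tzs[schedule$category == "admission_day" &
                                  schedule$ward %in% "icu"]
  dg <- encounter$days_general
  di <- encounter$days_icu
  if (dg > 0) total <- total + dg * min(gen)
  if (di > 0) total <- total + di * min(icu)
  if (isTRUE(encounter$died)) {
    total <- total + sum(schedule$unit_cost_tzs[schedule$category == "death_expense"])
  }
  total
}

# literal threshold arithmetic for one patient
oracle_classify <- function(oop, te, nse, income, h_a, rate = 2339) {
  che_10 <- if (te == 0) oop > 0 else oop >= 0.10 * te
  che_25 <- if (te == 0) oop > 0 else oop >= 0.25 * te
  che_40 <- if (nse == 0) oop > 0 else oop >= 0.40 * nse
  lines_annual <- c(national = 49320 * 12,
                    usd190 = 1.90 * 365 * rate,
                    usd320 = 3.20 * 365 * rate)
  rem <- max(income - oop, 0) / h_a
  imp <- rem < lines_annual
  list(che = c(che_10, che_25, che_40), any_che = che_10 || che_25 || che_40,
       imp = unname(imp), any_imp = any(imp))
}

# sort-and-slice subsistence oracle
oracle_subsistence <- function(te, food, lo = 45, hi = 55) {
  ord <- order(te)
  n <- length(te)
  pct <- 100 * (seq_len(n) - 0.5) / n
  sel <- ord[pct >= lo & pct <= hi]
  if (length(sel) == 0) sel <- ord[which.min(abs(pct - (lo + hi) / 2))]
  mean(food[sel])
}

# minimal valid household table
make_households <- function(n, te, food, income, n_adults = 2, n_children = 1,
                            income_missing = rep(FALSE, n)) {
  tibble::tibble(
    patient_id = sprintf("H%03d", seq_len(n)),
    n_adults = rep_len(n_adults, n), n_children = rep_len(n_children, n),
    n_dependents = rep_len(n_children, n),
    dependents_bracket = "0-2",
    annual_income = rep_len(income, n),
    annual_total_expenditure = rep_len(te, n),
    annual_food_expenditure = rep_len(food, n),
    income_missing = income_missing
  )
}
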