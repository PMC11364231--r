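#' Classify encounters into Three-Delays profiles
#'
#' Maps the raw prehospital fields of each encounter onto the Three-Delays
#' framework: Delay 1 (the decision to seek care) is represented by the
#' recorded markers — cost concern, perceived injury severity, and needing
#' another person's permission/agency; Delay 2 (reaching an appropriate
#' facility) by the number of inter-facility transfers and whether surgery
#' followed a transfer; Delay 3 (receiving care on arrival) by the ordinal
#' time-to-care category `minutes`, `hours`, or `longer`. Missing raw fields
#' become explicit `"unknown"` markers rather than errors.
#'
#' @param encounters Encounter tibble (see [generate_cohort()]).
#' @return Tibble: `patient_id`, `delay1_cost_concern`,
#'   `delay1_perceived_severe`, `delay1_agency`, `transfers`,
#'   `surgery_after_transfer`, `time_to_care_category`.
#' @export
classify_delays <- function(encounters) {
  tt <- encounters$time_to_care
  if (is.null(tt)) tt <- rep(NA_character_, nrow(encounters))
  bad_tt <- !is.na(tt) & !tt %in% c("minutes", "hours", "longer")
  if (any(bad_tt)) {
    fintox_error(paste0("unrecognized time_to_care value(s): ",
                        paste(unique(tt[bad_tt]), collapse = ", ")),
                 "fintox_validation_error")
  }
  transfers <- encounters$n_transfers
  if (is.null(transfers)) transfers <- rep(NA_real_, nrow(encounters))
  if (any(transfers < 0, na.rm = TRUE)) {
    fintox_error("transfer counts must be non-negative", "fintox_validation_error")
  }
  get_flag <- function(col) {
    x <- encounters[[col]]
    if (is.null(x)) rep(NA, nrow(encounters)) else x
  }
  tibble::tibble(
    patient_id = encounters$patient_id,
    delay1_cost_concern = get_flag("delay1_cost_concern"),
    delay1_perceived_severe = get_flag("delay1_perceived_severe"),
    delay1_agency = get_flag("delay1_agency"),
    transfers = transfers,
    surgery_after_transfer = get_flag("surgery_after_transfer"),
    time_to_care_category = ifelse(is.na(tt), "unknown", tt)
  )
}

#' Summarize the Three Delays stratified by financial-toxicity status
#'
#' For each stratum (`any` vs `none` of the chosen toxicity flag) reports the
#' Delay-1 marker frequencies, the transfer distribution (Delay 2), the
#' time-to-care category proportions (Delay 3), the stratum's median OOP
#' cost, and the ratio of the toxic stratum's median OOP to the non-toxic
#' stratum's.
#'
#' @param profiles Output of [classify_delays()].
#' @param results A [toxicity_table()].
#' @param stratifier `"che"` or `"imp"`.
#' @return A list with tibble `summary` (one row per stratum x measure),
#'   `stratum_sizes`, and `oop_median_ratio`.
#' @export
delays_summary <- function(profiles, results, stratifier = c("che", "imp")) {
  stratifier <- match.arg(stratifier)
  any_col <- if (stratifier == "che") "any_che" else "any_imp"
  dat <- dplyr::left_join(profiles, results, by = "patient_id")
  strata <- list(any = dat[[any_col]] %in% TRUE,
                 none = dat[[any_col]] %in% FALSE)
  rows <- list()
  for (s in names(strata)) {
    sub <- dat[strata[[s]], , drop = FALSE]
    n <- nrow(sub)
    emit <- function(measure, category, value) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        stratum = s, measure = measure, category = category,
        value = value, n = n)
    }
    for (f in c("delay1_cost_concern", "delay1_perceived_severe", "delay1_agency")) {
      emit("delay1_factor_pct", f,
           if (n > 0) round(100 * mean(sub[[f]], na.rm = TRUE), 1) else NA_real_)
    }
    emit("transfers_mean", "transfers",
         if (n > 0) mean(sub$transfers, na.rm = TRUE) else NA_real_)
    emit("transfers_pct_any", "transfers",
         if (n > 0) round(100 * mean(sub$transfers > 0, na.rm = TRUE), 1) else NA_real_)
    emit("surgery_after_transfer_pct", "surgery_after_transfer",
         if (n > 0) round(100 * mean(sub$surgery_after_transfer, na.rm = TRUE), 1)
         else NA_real_)
    known <- sub$time_to_care_category[sub$time_to_care_category != "unknown"]
    for (lev in c("minutes", "hours", "longer")) {
      emit("time_to_care_pct", lev,
           if (length(known) > 0) round(100 * mean(known == lev), 1) else NA_real_)
    }
    emit("oop_median", "oop", if (n > 0) unname(median_iqr(sub$oop)[1]) else NA_real_)
  }
  summary <- dplyr::bind_rows(rows)
  med_any <- summary$value[summary$stratum == "any" & summary$measure == "oop_median"]
  med_none <- summary$value[summary$stratum == "none" & summary$measure == "oop_median"]
  ratio <- if (length(med_none) == 1 && !is.na(med_none) && med_none > 0 &&
               !is.na(med_any)) round(med_any / med_none, 2) else NA_real_
  list(summary = summary,
       stratum_sizes = vapply(strata, sum, integer(1)),
       oop_median_ratio = ratio)
}

#' Render a delays summary as a markdown panel
#'
#' @param ds A [delays_summary()] result.
#' @param stratifier Label used in the panel heading.
#' @return Markdown character scalar with one column block per delay.
#' @export
render_delays_markdown <- function(ds, stratifier = "toxicity") {
  s <- ds$summary
  line <- function(measure, category) {
    a <- s$value[s$stratum == "any" & s$measure == measure & s$category == category]
    b <- s$value[s$stratum == "none" & s$measure == measure & s$category == category]
    sprintf("%s: any %s / none %s", category,
            format(round(a, 1)), format(round(b, 1)))
  }
  paste(c(
    paste0("### Three Delays, stratified by ", stratifier,
           " (any n=", ds$stratum_sizes[["any"]],
           ", none n=", ds$stratum_sizes[["none"]], ")"),
    "", "**Delay 1 — deciding to seek care (% with marker)**",
    line("delay1_factor_pct", "delay1_cost_concern"),
    line("delay1_factor_pct", "delay1_perceived_severe"),
    line("delay1_factor_pct", "delay1_agency"),
    "", "**Delay 2 — reaching care**",
    line("transfers_mean", "transfers"),
    line("surgery_after_transfer_pct", "surgery_after_transfer"),
    "", "**Delay 3 — receiving care (% by time to care)**",
    line("time_to_care_pct", "minutes"),
    line("time_to_care_pct", "hours"),
    line("time_to_care_pct", "longer"),
    "", sprintf("Median OOP ratio (any / none): %s",
                format(ds$oop_median_ratio))
  ), collapse = "\n")
}
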