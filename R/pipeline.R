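#' Configuration for a full pipeline run
#'
#' @param cohort_dir Directory holding `households.csv`, `encounters.csv`,
#'   `services.csv` (as written by [write_fixture()]).
#' @param outdir Output directory; created if absent.
#' @param schedule_path Fee-schedule CSV; `NULL` uses the bundled synthetic
#'   schedule.
#' @param rate TZS per USD.
#' @param che_fractions,che_bases,che_comparison Passed to [che_config()].
#' @param lines A [poverty_lines()] tibble.
#' @param imp_mode `"absolute"` or `"newly_poor"`.
#' @param window Subsistence percentile window.
#' @param seed Recorded in the run metadata (the pipeline itself is
#'   deterministic).
#' @return A `fintox_run_config` list.
#' @export
run_config <- function(cohort_dir, outdir, schedule_path = NULL,
                       rate = TZS_PER_USD,
                       che_fractions = c(0.10, 0.25, 0.40),
                       che_bases = c("te", "te", "nse"),
                       che_comparison = "ge",
                       lines = poverty_lines(),
                       imp_mode = "absolute",
                       window = c(45, 55),
                       seed = 1L) {
  if (!dir.exists(cohort_dir)) {
    fintox_error(paste0("cohort directory not found: ", cohort_dir),
                 "fintox_validation_error")
  }
  if (!is.null(schedule_path) && !file.exists(schedule_path)) {
    fintox_error(paste0("fee schedule not found: ", schedule_path),
                 "fintox_validation_error")
  }
  structure(list(cohort_dir = cohort_dir, outdir = outdir,
                 schedule_path = schedule_path, rate = rate,
                 cfg = che_config(che_fractions, che_bases, che_comparison),
                 lines = lines, imp_mode = imp_mode, window = window,
                 seed = as.integer(seed)),
            class = "fintox_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys: `cohort_dir`, `outdir`, `schedule_path`, `rate`,
#' `che: {fractions, bases, comparison}`, `poverty_lines:` (list of
#' `{label, amount, currency, period}`), `imp_mode`, `window`, `seed`.
#'
#' @param path YAML file.
#' @return A `fintox_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  lines <- if (is.null(y$poverty_lines)) poverty_lines() else {
    df <- dplyr::bind_rows(lapply(y$poverty_lines, tibble::as_tibble))
    poverty_lines(df$label, df$amount, df$currency, df$period)
  }
  run_config(
    cohort_dir = y$cohort_dir, outdir = y$outdir,
    schedule_path = y$schedule_path,
    rate = y$rate %||% TZS_PER_USD,
    che_fractions = unlist(y$che$fractions) %||% c(0.10, 0.25, 0.40),
    che_bases = unlist(y$che$bases) %||% c("te", "te", "nse"),
    che_comparison = y$che$comparison %||% "ge",
    lines = lines,
    imp_mode = y$imp_mode %||% "absolute",
    window = unlist(y$window) %||% c(45, 55),
    seed = y$seed %||% 1L
  )
}

#' Run the full financial-toxicity pipeline
#'
#' Costing, toxicity classification, stratified tables, delays summary, and
#' a machine-readable metrics file, written under `config$outdir`. Identical
#' inputs produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report bundle: `costs`, `toxicity`, `tables`,
#'   `delays`, `metrics`, and `paths` of files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fintox_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fintox_error(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   "fintox_pipeline_error")
    })
  }
  cohort <- stage("load_cohort", read_cohort(config$cohort_dir))
  schedule <- stage("load_schedule",
                    if (is.null(config$schedule_path)) default_fee_schedule()
                    else load_fee_schedule(config$schedule_path))
  costs <- stage("costing", cost_cohort(schedule, cohort$encounters, cohort$services))
  toxicity <- stage("toxicity",
                    toxicity_table(cohort$households, costs, cfg = config$cfg,
                                   lines = config$lines, rate = config$rate,
                                   imp_mode = config$imp_mode,
                                   window = config$window))
  tab_che <- stage("table_che", build_stratified_table(cohort, toxicity, "che"))
  tab_imp <- stage("table_imp", build_stratified_table(cohort, toxicity, "imp"))
  profiles <- stage("delays", classify_delays(cohort$encounters))
  del_che <- stage("delays_che", delays_summary(profiles, toxicity, "che"))
  del_imp <- stage("delays_imp", delays_summary(profiles, toxicity, "imp"))
  metrics <- stage("metrics",
                   pipeline_metrics(cohort, costs, toxicity, del_che, del_imp, config))

  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  paths <- c(costs = file.path(config$outdir, "costs.csv"),
             toxicity = file.path(config$outdir, "toxicity.csv"),
             table_che = file.path(config$outdir, "table_che.csv"),
             table_imp = file.path(config$outdir, "table_imp.csv"),
             table_che_md = file.path(config$outdir, "table_che.md"),
             table_imp_md = file.path(config$outdir, "table_imp.md"),
             delays_che = file.path(config$outdir, "delays_che.csv"),
             delays_imp = file.path(config$outdir, "delays_imp.csv"),
             metrics = file.path(config$outdir, "metrics.json"),
             report = file.path(config$outdir, "report.md"))
  readr::write_csv(costs, paths[["costs"]], progress = FALSE)
  readr::write_csv(toxicity, paths[["toxicity"]], progress = FALSE)
  readr::write_csv(tab_che, paths[["table_che"]], progress = FALSE)
  readr::write_csv(tab_imp, paths[["table_imp"]], progress = FALSE)
  writeLines(render_stratified_markdown(tab_che), paths[["table_che_md"]])
  writeLines(render_stratified_markdown(tab_imp), paths[["table_imp_md"]])
  readr::write_csv(del_che$summary, paths[["delays_che"]], progress = FALSE)
  readr::write_csv(del_imp$summary, paths[["delays_imp"]], progress = FALSE)
  jsonlite::write_json(metrics, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  bundle <- list(costs = costs, toxicity = toxicity,
                 tables = list(che = tab_che, imp = tab_imp),
                 delays = list(che = del_che, imp = del_imp),
                 metrics = metrics, paths = paths)
  writeLines(render_report(bundle), paths[["report"]])
  invisible(bundle)
}

pipeline_metrics <- function(cohort, costs, toxicity, del_che, del_imp, config) {
  n <- nrow(cohort$households)
  n_income_missing <- sum(cohort$households$income_missing)
  n_imp_eligible <- n - n_income_missing
  h_a <- toxicity$h_a
  income_pae_monthly <- cohort$households$annual_income / (12 * h_a)
  flag_counts <- function(cols) {
    setNames(lapply(cols, function(cl) sum(toxicity[[cl]], na.rm = TRUE)), cols)
  }
  che_cols <- grep("^che_", names(toxicity), value = TRUE)
  imp_cols <- grep("^imp_", names(toxicity), value = TRUE)
  med_oop <- unname(median_iqr(toxicity$oop)[1])
  med_inc <- unname(median_iqr(income_pae_monthly)[1])
  any_che <- toxicity$any_che %in% TRUE
  any_imp_known <- toxicity$any_imp
  list(
    n = n,
    n_income_missing = n_income_missing,
    n_imp_eligible = n_imp_eligible,
    seed = config$seed,
    tzs_per_usd = config$rate,
    subsistence_expenditure_tzs = attr(toxicity, "subsistence_expenditure"),
    n_any_che = sum(any_che),
    n_any_imp = sum(any_imp_known, na.rm = TRUE),
    any_che_prevalence_pct = prevalence(toxicity$any_che, n),
    any_imp_prevalence_pct = prevalence(any_imp_known, n),
    any_imp_prevalence_pct_excluding_missing =
      if (n_imp_eligible > 0) prevalence(any_imp_known, n_imp_eligible) else NA,
    che_counts = flag_counts(setdiff(che_cols, "any_che")),
    imp_counts = flag_counts(setdiff(imp_cols, "any_imp")),
    median_oop_tzs = med_oop,
    median_oop_usd = convert_tzs_to_usd(med_oop, config$rate, "integer"),
    median_income_monthly_pae_tzs = med_inc,
    median_income_monthly_pae_usd = convert_tzs_to_usd(med_inc, config$rate, "integer"),
    income_ratio_nonche_vs_che = safe_ratio(
      income_pae_monthly[!any_che], income_pae_monthly[any_che]),
    income_ratio_nonimp_vs_imp = safe_ratio(
      income_pae_monthly[any_imp_known %in% FALSE],
      income_pae_monthly[any_imp_known %in% TRUE]),
    oop_ratio_che_vs_nonche = del_che$oop_median_ratio,
    oop_ratio_imp_vs_nonimp = del_imp$oop_median_ratio
  )
}

safe_ratio <- function(a, b) {
  tryCatch(ratio_of_medians(a, b), fintox_error = function(e) NA_real_)
}

#' Render the report bundle as a markdown document
#'
#' Every number in the document comes from the bundle's metrics and tables;
#' nothing is recomputed at render time.
#'
#' @param bundle The bundle returned by [run_pipeline()].
#' @return Markdown character scalar.
#' @export
render_report <- function(bundle) {
  need <- c("metrics", "tables", "delays")
  missing <- need[!need %in% names(bundle)]
  if (length(missing) > 0) {
    fintox_error(paste0("incomplete bundle, missing section(s): ",
                        paste(missing, collapse = ", ")),
                 "fintox_validation_error")
  }
  m <- bundle$metrics
  headline <- if (m$n == 0) "No patients in cohort (n=0)." else sprintf(
    paste0("Of %d acute-injury patients, %.1f%% (n = %d) experienced some form ",
           "of catastrophic health expenditure and %.1f%% (n = %d) an ",
           "impoverishing expense. Median OOP cost was %s TZS ($%d USD); ",
           "median monthly adult-equivalent household income was %s TZS ",
           "($%d USD)."),
    m$n, m$any_che_prevalence_pct, m$n_any_che,
    m$any_imp_prevalence_pct, m$n_any_imp,
    format(round(m$median_oop_tzs, 1), big.mark = ","), m$median_oop_usd,
    format(round(m$median_income_monthly_pae_tzs, 1), big.mark = ","),
    m$median_income_monthly_pae_usd)
  paste(c(
    "# Financial toxicity report", "",
    headline, "",
    sprintf("Patients excluded from impoverishment columns for missing income: %d.",
            m$n_income_missing), "",
    "## Characteristics stratified by CHE status", "",
    render_stratified_markdown(bundle$tables$che), "",
    "## Characteristics stratified by IMP status", "",
    render_stratified_markdown(bundle$tables$imp), "",
    "## Three Delays", "",
    render_delays_markdown(bundle$delays$che, "CHE"), "",
    render_delays_markdown(bundle$delays$imp, "IMP"), ""
  ), collapse = "\n")
}
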