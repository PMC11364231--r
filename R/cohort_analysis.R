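#' Median and interquartile range
#'
#' Quantiles use the default linear-interpolation definition
#' (`stats::quantile` type 7), matching the "Median [IQR]" presentation of
#' registry descriptives.
#'
#' @param values Numeric vector; `NA`s dropped.
#' @return Named numeric vector `c(median = , iqr = )`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5)) # median 3, iqr 2
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    fintox_error("median_iqr needs at least one non-missing value",
                 "fintox_validation_error")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Prevalence as a percentage
#'
#' @param flags Logical vector (`NA` counts as not flagged).
#' @param denominator Denominator; defaults to `length(flags)`. Using the
#'   full cohort size while flags carry `NA` for excluded patients reproduces
#'   headline prevalences whose denominator retains the exclusions.
#' @param digits Rounding for reporting (default 1 dp); use `NULL` for the
#'   exact value.
#' @return Percentage.
#' @export
#' @examples
#' prevalence(rep(c(TRUE, FALSE), c(49, 29))) # 62.8
prevalence <- function(flags, denominator = length(flags), digits = 1) {
  if (denominator <= 0) {
    fintox_error("prevalence denominator must be positive", "fintox_validation_error")
  }
  k <- sum(flags, na.rm = TRUE)
  if (k > denominator) {
    fintox_error("more flagged cases than the denominator", "fintox_validation_error")
  }
  pct <- 100 * k / denominator
  if (is.null(digits)) pct else round(pct, digits)
}

#' Ratio of group medians
#'
#' @param group_a,group_b Numeric vectors (e.g. incomes of non-CHE vs CHE
#'   households).
#' @param digits Rounding for reporting (default 2 dp); `NULL` for exact.
#' @return `median(group_a) / median(group_b)`.
#' @export
#' @examples
#' ratio_of_medians(157894.7, 62500) # 2.53
ratio_of_medians <- function(group_a, group_b, digits = 2) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0) {
    fintox_error("both groups must be non-empty", "fintox_validation_error")
  }
  mb <- median(group_b)
  if (mb == 0) {
    fintox_error("denominator group has median zero; ratio undefined",
                 "fintox_undefined_ratio_error")
  }
  r <- median(group_a) / mb
  if (is.null(digits)) r else round(r, digits)
}

#' Compare a variable across strata
#'
#' Continuous variables are compared by Welch two-sample t-test (two groups)
#' or one-way ANOVA (more than two); categorical variables by chi-square test
#' on the contingency table. The method used is recorded in the result.
#'
#' @param values Numeric or categorical vector.
#' @param groups Group labels, same length.
#' @return Tibble with `method`, `statistic`, `p_value`.
#' @export
group_compare <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) {
    fintox_error("group comparison needs at least two non-empty groups",
                 "fintox_degenerate_group_error")
  }
  if (is.numeric(values)) {
    if (min(table(groups)) < 2) {
      fintox_error("each group needs at least two values for a mean comparison",
                   "fintox_degenerate_group_error")
    }
    if (nlevels(groups) == 2) {
      fit <- t.test(values ~ groups)
      tibble::tibble(method = "welch_t", statistic = unname(fit$statistic),
                     p_value = fit$p.value)
    } else {
      fit <- summary(aov(values ~ groups))[[1]]
      tibble::tibble(method = "anova_f", statistic = fit$`F value`[1],
                     p_value = fit$`Pr(>F)`[1])
    }
  } else {
    tab <- table(values, groups)
    fit <- suppressWarnings(chisq.test(tab))
    tibble::tibble(method = "chi_square", statistic = unname(fit$statistic),
                   p_value = fit$p.value)
  }
}

# significance stars as footnoted in the stratified tables
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# variables summarised in the stratified tables: continuous ones as
# median [IQR], the rest as % (n) with unknowns kept in the denominator
TABLE_VARIABLES <- list(
  continuous = c(age = "age",
                 income_monthly_pae = "income_monthly_pae",
                 oop = "oop"),
  categorical = c(sex = "sex", education = "education", region = "region",
                  marital_status = "marital_status", occupation = "occupation",
                  dependents_bracket = "dependents_bracket",
                  insurance = "insurance", mechanism = "mechanism",
                  hospitalized = "hospitalized", surgery = "surgery")
)

#' Stratified descriptive table
#'
#' Builds the demographic/financial/medical characteristics table stratified
#' by financial-toxicity status: strata are `overall`, `any`, `none`, and one
#' stratum per individual threshold (CHE) or poverty line (IMP) — the
#' per-threshold strata overlap and are each contained in `any`. Categorical
#' cells carry `n` and percentage (unknown responses are counted in the
#' denominator); continuous cells carry median and IQR. Each variable also
#' receives an any-vs-none comparison from [group_compare()]. For the IMP
#' stratifier, patients with missing income are dropped from every stratum
#' but retained in `overall`.
#'
#' @param cohort A cohort list (`households` + `encounters`) as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param results A [toxicity_table()].
#' @param stratifier `"che"` or `"imp"`.
#' @return A `fintox_stratified_table` tibble in long format: `variable`,
#'   `category`, `stratum`, `n`, `pct`, `median`, `iqr`, `method`,
#'   `p_value`, `stars` (comparison columns populated on the first row of
#'   each variable).
#' @export
build_stratified_table <- function(cohort, results, stratifier = c("che", "imp")) {
  stratifier <- match.arg(stratifier)
  dat <- dplyr::left_join(cohort$encounters, cohort$households, by = "patient_id")
  res_cols <- c("patient_id", setdiff(names(results), names(dat)))
  dat <- dplyr::left_join(dat, results[, res_cols], by = "patient_id")
  dat$income_monthly_pae <- dat$annual_income / (12 * dat$h_a)
  flag_cols <- if (stratifier == "che") {
    grep("^che_", names(results), value = TRUE)
  } else {
    grep("^imp_", names(results), value = TRUE)
  }
  any_col <- if (stratifier == "che") "any_che" else "any_imp"

  eligible <- if (stratifier == "imp") !dat$income_missing else rep(TRUE, nrow(dat))
  strata <- c(list(overall = rep(TRUE, nrow(dat)),
                   any = eligible & dat[[any_col]] %in% TRUE,
                   none = eligible & dat[[any_col]] %in% FALSE),
              setNames(lapply(flag_cols, function(cl) eligible & dat[[cl]] %in% TRUE),
                       flag_cols))

  rows <- list()
  for (v in TABLE_VARIABLES$continuous) {
    cmp <- compare_any_none(dat[[v]], dat, any_col, eligible)
    for (s in names(strata)) {
      vals <- dat[[v]][strata[[s]]]
      vals <- vals[!is.na(vals)]
      mi <- if (length(vals) > 0) median_iqr(vals) else c(median = NA_real_, iqr = NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, category = "median_iqr", stratum = s,
        n = length(vals), pct = NA_real_,
        median = mi[["median"]], iqr = mi[["iqr"]],
        method = cmp$method, p_value = cmp$p_value, stars = p_stars(cmp$p_value))
      cmp <- list(method = NA_character_, p_value = NA_real_)
    }
  }
  for (v in TABLE_VARIABLES$categorical) {
    x <- as.character(dat[[v]])
    cats <- sort(unique(x[!is.na(x)]))
    cmp <- compare_any_none(x, dat, any_col, eligible)
    first <- TRUE
    for (cat in cats) {
      for (s in names(strata)) {
        denom <- sum(strata[[s]])           # unknowns included in denominator
        nn <- sum(strata[[s]] & x %in% cat)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, category = cat, stratum = s,
          n = nn, pct = if (denom > 0) round(100 * nn / denom, 1) else NA_real_,
          median = NA_real_, iqr = NA_real_,
          method = if (first) cmp$method else NA_character_,
          p_value = if (first) cmp$p_value else NA_real_,
          stars = if (first) p_stars(cmp$p_value) else "")
        first <- FALSE
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "stratifier") <- stratifier
  attr(out, "stratum_sizes") <- vapply(strata, sum, integer(1))
  class(out) <- c("fintox_stratified_table", class(out))
  out
}

compare_any_none <- function(x, dat, any_col, eligible) {
  keep <- eligible & !is.na(dat[[any_col]])
  res <- tryCatch(group_compare(x[keep], dat[[any_col]][keep]),
                  fintox_error = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(res)) list(method = NA_character_, p_value = NA_real_) else
    list(method = res$method, p_value = res$p_value)
}

#' Render a stratified table as markdown
#'
#' @param table A [build_stratified_table()] result.
#' @return A character scalar of markdown (one row per variable/category,
#'   "% (n)" or "median [IQR]" cells, p-value stars footnoted).
#' @export
render_stratified_markdown <- function(table) {
  strata <- unique(table$stratum)
  sizes <- attr(table, "stratum_sizes")
  header <- paste0("| Variable | Category | ",
                   paste0(strata, " (n=", sizes[strata], ")", collapse = " | "),
                   " | p |")
  sep <- paste0("|", paste(rep("---|", length(strata) + 3), collapse = ""))
  body <- character(0)
  for (v in unique(table$variable)) {
    sub <- table[table$variable == v, , drop = FALSE]
    for (cat in unique(sub$category)) {
      cells <- vapply(strata, function(s) {
        r <- sub[sub$category == cat & sub$stratum == s, , drop = FALSE]
        if (nrow(r) == 0) return("")
        if (cat == "median_iqr") {
          sprintf("%s [%s]", format(round(r$median, 1), big.mark = ","),
                  format(round(r$iqr, 1), big.mark = ","))
        } else {
          sprintf("%.1f (%d)", r$pct, r$n)
        }
      }, character(1))
      p <- sub$p_value[sub$category == cat & sub$stratum == strata[1]]
      stars <- sub$stars[sub$category == cat & sub$stratum == strata[1]]
      pcell <- if (length(p) == 1 && !is.na(p)) paste0(format(round(p, 3)), stars) else ""
      body <- c(body, paste0("| ", v, " | ", cat, " | ",
                             paste(cells, collapse = " | "), " | ", pcell, " |"))
    }
  }
  paste(c(header, sep, body,
          "", "p<0.05\\*; p<0.01\\*\\*; p<0.001\\*\\*\\*"),
        collapse = "\n")
}
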