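#' Feighner-criteria alcohol-dependence diagnosis
#'
#' The Feighner diagnosis requires at least one symptom in three of four
#' problem categories (medical consequences; attempts to control drinking;
#' legal/social problems; self-reported excessive drinking). Given the
#' earliest symptom age in each category (or `NA` when the category was
#' never endorsed), the age at first problem is the earliest category age
#' and the age of onset is the age at which the third category became
#' positive — the third-smallest endorsed age (ties share a value).
#'
#' @param category_ages numeric vector of length 4: earliest symptom age per
#'   category, `NA` = category not endorsed.
#' @return list with `diagnosis` (logical), `first_problem_age` and
#'   `onset_age` (both `NA` when not diagnosed).
#' @export
#' @examples
#' feighner_diagnosis(c(14, 16, 21, NA))  # diagnosed, onset 21
feighner_diagnosis <- function(category_ages) {
  stop_if(length(category_ages) != 4, "exactly four category ages required")
  stop_if(any(stats::na.omit(category_ages) < 0), "ages must be non-negative")
  ages <- unname(sort(category_ages[!is.na(category_ages)]))
  if (length(ages) < 3) {
    return(list(diagnosis = FALSE, first_problem_age = NA_real_,
                onset_age = NA_real_))
  }
  list(diagnosis = TRUE, first_problem_age = ages[1], onset_age = ages[3])
}

#' DSM-V alcohol-use-disorder severity
#'
#' Maps the number of DSM-V conceptual areas endorsed to the severity
#' grade: fewer than 2 = no disorder, 2-3 = mild, 4-5 = moderate, 6 or more
#' = severe.
#'
#' @param criteria_count non-negative integer count(s) of endorsed criteria.
#' @return ordered factor with levels `no_disorder < mild < moderate <
#'   severe`.
#' @export
#' @examples
#' dsm5_severity(c(0, 2, 4, 6))
dsm5_severity <- function(criteria_count) {
  stop_if(any(criteria_count < 0), "criteria count must be non-negative")
  cut(criteria_count, breaks = c(-Inf, 1, 3, 5, Inf),
      labels = c("no_disorder", "mild", "moderate", "severe"),
      ordered_result = TRUE)
}

#' Severity distribution of a cohort
#'
#' Counts and percentages per DSM-V severity grade, plus the mean and
#' sample standard deviation of the criteria counts.
#'
#' @param criteria_counts integer vector of per-subject DSM-V criteria
#'   counts.
#' @return list with `table` (severity, n, percent to 1 d.p.), `mean` and
#'   `sd` (n-1 denominator), both to 2 d.p., and `n`.
#' @export
#' @examples
#' d <- severity_distribution(rep(c(3, 4, 6), c(1, 14, 38)))
#' d$table
severity_distribution <- function(criteria_counts) {
  stop_if(length(criteria_counts) == 0, "empty cohort")
  sev <- dsm5_severity(criteria_counts)
  n <- table(sev)
  out <- data.frame(severity = names(n), n = as.integer(n),
                    percent = round_half_up(100 * as.integer(n) /
                                              length(criteria_counts), 1),
                    stringsAsFactors = FALSE)
  list(table = out,
       mean = round_half_up(mean(criteria_counts), 2),
       sd = round_half_up(stats::sd(criteria_counts), 2),
       n = length(criteria_counts))
}

#' Read a phenotype symptom table
#'
#' Tab-separated, columns `sample_id`, `cat1_age` .. `cat4_age` (earliest
#' symptom age per Feighner category, empty = not endorsed) and
#' `dsm5_count`.
#'
#' @param path path to the TSV.
#' @return typed data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv(path)
  check_columns(ph, c("sample_id", "cat1_age", "cat2_age", "cat3_age",
                      "cat4_age", "dsm5_count"), "phenotype table")
  for (col in c("cat1_age", "cat2_age", "cat3_age", "cat4_age"))
    ph[[col]] <- as.numeric(ph[[col]])
  ph$dsm5_count <- as.integer(ph$dsm5_count)
  ph
}
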