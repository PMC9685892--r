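#' Published summary tables for the reference transfer cohort
#'
#' Packaged transcriptions of the published summary tables from the
#' retrospective interhospital-transfer study this pipeline is built
#' around (8,893 adult critical-care transfers within one health system,
#' 2010-2017): cohort demographics and discharge dispositions, the
#' highest-prevalence diagnosis combinations (printed lift and percent),
#' and the highest-mortality-impact combinations (printed coverage,
#' confidence, unadjusted and adjusted odds ratios with 95% CIs). These
#' printed numbers are inputs to the consistency checks; the underlying
#' patient-level data are not publicly available.
#'
#' @return a list with data frames `demographics`, `prevalence`,
#'   `mortality`, plus scalars `N` (patients) and `D` (in-hospital
#'   deaths).
#' @export
published_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "ihtrules",
                               mustWork = TRUE)
  demographics <- read.csv(p("published_cohort_demographics.csv"),
                           stringsAsFactors = FALSE)
  prevalence <- read.csv(p("published_prevalence_rules.csv"),
                         stringsAsFactors = FALSE)
  mortality <- read.csv(p("published_mortality_rules.csv"),
                        stringsAsFactors = FALSE)
  disp <- demographics[demographics$block == "disposition", ]
  N <- sum(disp$n)
  D <- disp$n[disp$level == "Died"]
  list(demographics = demographics, prevalence = prevalence,
       mortality = mortality, N = N, D = D)
}

#' Baseline mortality from the published disposition totals
#'
#' @param tables output of [published_tables()] (loaded if omitted).
#' @param digits display decimals (default 1).
#' @return list with `deaths`, `patients` and `percent` (rounded).
#' @export
baseline_mortality <- function(tables = published_tables(), digits = 1) {
  list(deaths = tables$D, patients = tables$N,
       percent = round(100 * tables$D / tables$N, digits))
}

#' Check the lift identity on the published prevalence rows
#'
#' The printed "lift" column of the published prevalence table equals the
#' printed percent (rule confidence) divided by the baseline mortality
#' `D/N`, to 2 decimal places, for most rows. This check recomputes the
#' lift from each row's confidence and classifies every row: `match`
#' (recomputed 2-d.p. value equals the printed one), `boundary` (they
#' differ by exactly 0.01 — the printed 1-d.p. confidence leaves the
#' second lift decimal undetermined), or `mismatch`.
#'
#' @param tables output of [published_tables()].
#' @return the prevalence table with columns `lift_computed` and `status`.
#' @export
check_lift_identity <- function(tables = published_tables()) {
  baseline <- tables$D / tables$N
  tab <- tables$prevalence
  tab$lift_computed <- round(tab$confidence_pct / 100 / baseline, 2)
  diff <- abs(tab$lift_computed - tab$lift)
  tab$status <- ifelse(diff < 0.005, "match",
                       ifelse(diff < 0.015, "boundary", "mismatch"))
  tab
}

#' Reconstruct and check unadjusted odds ratios from printed percentages
#'
#' For each published mortality-impact row, rebuilds the 2x2 table from
#' the printed coverage and confidence via [reconstruct_table()], computes
#' the odds ratio via [estimate_or()], and measures agreement with the
#' printed odds ratio as symmetric relative percent difference
#' (`200 |a - b| / (a + b)`), the standard agreement measure for
#' ratio-scale quantities. Rows with tiny printed coverage are dominated
#' by the rounding of the printed percentages, which is why checks are
#' usually restricted to `coverage >= min_coverage`.
#'
#' @param tables output of [published_tables()].
#' @param min_coverage smallest printed coverage (percent) to check
#'   (default 0.5).
#' @return a data frame with `or_computed`, `rel_diff_pct` and the
#'   printed values, one row per qualifying combination.
#' @export
check_or_reconstruction <- function(tables = published_tables(),
                                    min_coverage = 0.5) {
  tab <- tables$mortality
  tab <- tab[tab$coverage_pct >= min_coverage, , drop = FALSE]
  res <- lapply(seq_len(nrow(tab)), function(i) {
    ct <- reconstruct_table(tables$N, tables$D,
                            tab$coverage_pct[i], tab$confidence_pct[i])
    est <- estimate_or(ct)
    data.frame(antecedent = tab$antecedent[i],
               order = tab$order[i],
               coverage_pct = tab$coverage_pct[i],
               confidence_pct = tab$confidence_pct[i],
               or_printed = tab$or[i],
               or_computed = est$or,
               rel_diff_pct = 200 * abs(est$or - tab$or[i]) /
                 (est$or + tab$or[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
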