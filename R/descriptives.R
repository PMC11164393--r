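#' Pearson chi-square comparison of a contingency table
#'
#' Pearson's chi-square without continuity correction (the uncorrected
#' statistic is what reproduces published bivariate p-values in
#' epidemiological descriptive tables; Yates' correction does not).
#'
#' @param counts A 2xk (or rxk) matrix of counts, e.g. rows = category,
#'   columns = sex.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' categorical_compare(matrix(c(528, 447, 70, 66), 2))
categorical_compare <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) stop("expected counts must be positive",
                                  call. = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Compare a continuous measure between two groups, routing on normality
#'
#' Runs a Kolmogorov-Smirnov normality check per group (one-sample KS against
#' a normal with the group's mean and SD -- the Lilliefors caveat applies and
#' is documented) at `alpha`; when both groups look normal a two-sample
#' t-test is used, otherwise the Mann-Whitney (Wilcoxon rank-sum) test with
#' normal approximation and tie correction.
#'
#' @param values_f,values_m Numeric vectors (length >= 3 each).
#' @param alpha Normality-rejection level for the KS check.
#' @return A one-row tibble: `test` ("t" or "mann-whitney"), `statistic`,
#'   `p_value`, `normal_f`, `normal_m` (the KS verdicts).
#' @export
#' @examples
#' continuous_compare(rnorm(50), rnorm(50, 0.2))
continuous_compare <- function(values_f, values_m, alpha = 0.05) {
  values_f <- values_f[!is.na(values_f)]
  values_m <- values_m[!is.na(values_m)]
  if (length(values_f) < 3 || length(values_m) < 3) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  ks_normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)  # constant vector: not normal
    p <- suppressWarnings(
      stats::ks.test(v, "pnorm", mean = mean(v), sd = stats::sd(v))$p.value)
    p > alpha
  }
  nf <- ks_normal(values_f)
  nm <- ks_normal(values_m)
  if (stats::sd(values_f) == 0 && stats::sd(values_m) == 0) {
    warning("constant vectors: Mann-Whitney route with degenerate ranks")
  }
  if (nf && nm) {
    ht <- stats::t.test(values_f, values_m)
    test <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_f, values_m, exact = FALSE, correct = FALSE))
    test <- "mann-whitney"
  }
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value), normal_f = nf, normal_m = nm)
}

#' Sex-stratified descriptive summary of a cohort
#'
#' Builds the standard descriptive layout of an accuracy study: one row per
#' variable with Total / Female / Male columns and the p-value of the
#' between-sex comparison. Categorical variables (the per-criterion component
#' positivity rows, computed from exactly the same predicates as the
#' classifier -- a single source of truth for cutoffs -- plus any flags) use
#' Pearson chi-square; continuous measures use [continuous_compare()].
#'
#' @param cohort A classifiable canonical cohort tibble.
#' @param criteria Criteria whose component-positivity rows to include.
#' @return A tibble: `variable`, `type`, per-stratum summaries (`total`,
#'   `female`, `male` as "n (pct)" or "mean (sd)"), `test`, `p_value`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 150, seed = 11))
#' summarize_cohort(coh)
summarize_cohort <- function(cohort, criteria = mets_criteria()) {
  if (inherits(criteria, "mets_criterion")) criteria <- list(criteria)
  is_f <- cohort$sex == "female"
  n_f <- sum(is_f)
  n_m <- sum(!is_f)
  both <- n_f > 0 && n_m > 0

  pct_row <- function(variable, positive) {
    fmt <- function(k, n) if (n == 0) "-" else
      sprintf("%d (%.2f)", k, 100 * k / n)
    tab <- rbind(c(sum(positive & is_f), sum(positive & !is_f)),
                 c(sum(!positive & is_f), sum(!positive & !is_f)))
    p <- if (both && all(rowSums(tab) > 0)) {
      categorical_compare(tab)$p_value
    } else NA_real_
    tibble::tibble(
      variable = variable, type = "categorical",
      total = fmt(sum(positive), length(positive)),
      female = fmt(sum(positive & is_f), n_f),
      male = fmt(sum(positive & !is_f), n_m),
      test = if (is.na(p)) NA_character_ else "chi-square",
      p_value = p)
  }
  cont_row <- function(variable, values) {
    fmt <- function(v) if (!length(v)) "-" else
      sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
    cc <- if (both && n_f >= 3 && n_m >= 3) {
      continuous_compare(values[is_f], values[!is_f])
    } else NULL
    tibble::tibble(
      variable = variable, type = "continuous",
      total = fmt(values), female = fmt(values[is_f]),
      male = fmt(values[!is_f]),
      test = if (is.null(cc)) NA_character_ else cc$test,
      p_value = if (is.null(cc)) NA_real_ else cc$p_value)
  }

  cont_vars <- c(glucose_mgdl = "Fasting glucose (mg/dL)",
                 tg_mgdl = "Triglycerides (mg/dL)",
                 hdl_mgdl = "HDL cholesterol (mg/dL)",
                 waist_cm = "Waist circumference (cm)",
                 bmi = "BMI (kg/m2)",
                 sbp_mmhg = "Systolic blood pressure (mmHg)",
                 dbp_mmhg = "Diastolic blood pressure (mmHg)")
  rows <- purrr::imap(cont_vars, function(lab, col) {
    v <- cohort[[col]]
    if (all(is.na(v))) NULL else cont_row(lab, v[!is.na(v)])
  })

  comp_rows <- purrr::map(criteria, function(cr) {
    ev <- evaluate_components(cohort, cr)
    comps <- intersect(c("waist", "triglycerides", "hdl", "blood_pressure",
                         "glucose"), names(ev))
    purrr::map(comps, function(cp)
      pct_row(sprintf("%s positive [%s]", cp, cr$name), ev[[cp]]))
  })
  mets_rows <- purrr::map(criteria, function(cr) {
    pct_row(sprintf("MetS [%s]", cr$name),
            evaluate_components(cohort, cr)$mets)
  })

  dplyr::bind_rows(c(unname(purrr::compact(rows)),
                     unname(purrr::flatten(comp_rows)),
                     unname(mets_rows)))
}
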