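#' Run the full MetS accuracy analysis
#'
#' End-to-end orchestration: ingest (or simulate) a cohort, validate and
#' exclude non-classifiable records, classify under the requested
#' definitions, build the sex-stratified descriptive table, estimate overall
#' and by-sex prevalence per definition with exact CIs, and evaluate every
#' comparison definition against the gold standard (Se/Sp/PPV/NPV, likelihood
#' ratios, kappa with agreement band). Identical inputs and seed produce
#' identical outputs.
#'
#' @param cohort A canonical cohort tibble (e.g. from [read_cohort()] or
#'   [simulate_cohort()]), or `NULL` to simulate from `spec`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @param criteria A named list of [criterion_definition()]s; must contain
#'   `gold`.
#' @param gold Name of the gold-standard definition.
#' @param output_dir Optional directory: when given, writes
#'   `prevalence.csv`, `accuracy.csv`, `descriptives.csv`, `exclusions.csv`,
#'   a JSON bundle `report.json`, and `run_log.txt`.
#' @param level Confidence level for all intervals.
#' @return An object of class `mets_report`: a list with tibbles
#'   `prevalence`, `accuracy`, `descriptives`, `exclusions`, `labels`, and a
#'   `log` list (n ingested/kept/excluded, gold, seed, package version).
#' @export
#' @examples
#' rep <- run_mets_analysis(spec = cohort_spec(n = 150, seed = 5))
#' rep$prevalence
run_mets_analysis <- function(cohort = NULL, spec = NULL,
                              criteria = mets_criteria(),
                              gold = "IDF_AHA_NHLBI",
                              output_dir = NULL, level = 0.95) {
  if (is.null(cohort)) {
    if (is.null(spec)) stop("supply a cohort or a cohort_spec", call. = FALSE)
    cohort <- simulate_cohort(spec)
  }
  if (!gold %in% names(criteria)) {
    stop("gold standard `", gold, "` is not in the criteria list",
         call. = FALSE)
  }
  n_in <- nrow(cohort)
  fc <- filter_classifiable(cohort)
  kept <- fc$cohort
  if (nrow(kept) == 0L) stop("no classifiable records", call. = FALSE)

  labels <- classify_cohort(kept, criteria)

  prev <- purrr::map_dfr(names(criteria), function(nm) {
    dplyr::bind_rows(
      dplyr::mutate(prevalence(labels[[nm]], level = level),
                    criterion = nm, stratum = "overall"),
      purrr::map_dfr(c("female", "male"), function(sx) {
        mask <- labels$sex == sx
        if (!any(mask)) return(NULL)
        dplyr::mutate(prevalence(labels[[nm]], stratum = mask, level = level),
                      criterion = nm, stratum = sx)
      })
    )
  })
  prev <- dplyr::select(prev, "criterion", "stratum", dplyr::everything())

  acc <- compare_criteria(labels, gold = gold, level = level)
  desc <- summarize_cohort(kept, criteria)

  log <- list(
    package = "metsdx",
    version = as.character(utils::packageVersion("metsdx")),
    n_input = n_in, n_classifiable = nrow(kept),
    n_excluded = nrow(fc$exclusions),
    gold = gold, criteria = names(criteria),
    seed = if (!is.null(spec)) spec$seed else NULL,
    level = level
  )
  report <- structure(
    list(prevalence = prev, accuracy = acc, descriptives = desc,
         exclusions = fc$exclusions, labels = labels, log = log),
    class = "mets_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.mets_report <- function(x, ...) {
  cat("<mets_report> ", x$log$n_classifiable, " classifiable records (",
      x$log$n_excluded, " excluded), gold standard ", x$log$gold, "\n",
      sep = "")
  ov <- x$prevalence[x$prevalence$stratum == "overall", ]
  cat("prevalence (overall):\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-14s %5.2f%% (%.2f-%.2f)\n", ov$criterion[i],
                100 * ov$estimate[i], 100 * ov$conf_low[i],
                100 * ov$conf_high[i]))
  }
  kap <- x$accuracy[x$accuracy$metric == "kappa", ]
  cat("kappa vs ", x$log$gold, ":\n", sep = "")
  for (i in seq_len(nrow(kap))) {
    cat(sprintf("  %-14s %.4f  %s\n", kap$criterion[i], kap$estimate[i],
                kap$band[i]))
  }
  invisible(x)
}

#' Write a report bundle to disk (CSV tables + JSON + run log)
#' @param report A `mets_report`.
#' @param output_dir Directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$prevalence, file.path(output_dir, "prevalence.csv"))
  readr::write_csv(report$accuracy, file.path(output_dir, "accuracy.csv"))
  readr::write_csv(report$descriptives,
                   file.path(output_dir, "descriptives.csv"))
  readr::write_csv(report$exclusions, file.path(output_dir, "exclusions.csv"))
  jsonlite::write_json(
    list(log = report$log, prevalence = report$prevalence,
         accuracy = report$accuracy),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(
    c(paste0("metsdx ", report$log$version),
      paste0("records: ", report$log$n_input, " in, ",
             report$log$n_classifiable, " classifiable, ",
             report$log$n_excluded, " excluded"),
      paste0("gold standard: ", report$log$gold),
      paste0("criteria: ", paste(report$log$criteria, collapse = ", ")),
      paste0("seed: ", report$log$seed %||% "none")),
    file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' @rdname tidy.mets_report
#' @export
glance.mets_report <- function(x, ...) {
  tibble::tibble(n_input = x$log$n_input,
                 n_classifiable = x$log$n_classifiable,
                 n_excluded = x$log$n_excluded,
                 gold = x$log$gold,
                 n_criteria = length(x$log$criteria))
}

#' Broom-style tidiers for analysis reports
#'
#' `tidy()` returns the per-criterion accuracy metric table; `glance()` a
#' one-row run summary.
#'
#' @param x A `mets_report` from [run_mets_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mets_report <- function(x, ...) x$accuracy
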