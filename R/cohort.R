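#' Read a participant-level cohort table
#'
#' Ingests a deposited cohort spreadsheet (CSV/TSV, or XLSX when the readxl
#' package is installed) through a [mets_codebook()] mapping and returns a
#' tibble in the canonical layout of [cohort_fields()]. Rows are never
#' silently dropped: cells that fail coercion or violate an invariant are set
#' to `NA` and reported in the `problems` attribute (one row per offending
#' cell), leaving the record to be excluded -- with a reason -- by
#' [filter_classifiable()].
#'
#' @param path Path to a CSV/TSV/XLSX file.
#' @param codebook A [mets_codebook()]; defaults to the identity mapping.
#' @return A tibble with columns `id`, `sex`, the continuous measures and
#'   flags of [cohort_fields()], and derived `age_over_40`. Attributes:
#'   `provenance` (source path) and `problems` (tibble of row-level
#'   validation reports: `row`, `id`, `field`, `value`, `problem`).
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(simulate_cohort(cohort_spec(n = 5, seed = 1)), path)
#' coh <- read_cohort(path)
#' nrow(coh)
read_cohort <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!inherits(codebook, "mets_codebook")) {
    stop("`codebook` must be created with mets_codebook()", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package", call. = FALSE)
      }
      x <- readxl::read_excel(path)
      x[] <- lapply(x, as.character)
      x
    },
    stop("unsupported file extension: .", ext, call. = FALSE)
  )
  canonicalize_cohort(raw, codebook, provenance = path)
}

#' Coerce a raw data frame into the canonical cohort layout
#'
#' The workhorse behind [read_cohort()], exported so cohorts already held in
#' memory (e.g. read by other means) can be pushed through the same codebook
#' mapping, unit conversion and validation.
#'
#' @param data A data frame of character/numeric/logical columns.
#' @inheritParams read_cohort
#' @param provenance Optional source label stored as an attribute.
#' @return See [read_cohort()].
#' @export
canonicalize_cohort <- function(data, codebook = default_codebook(),
                                provenance = "in-memory") {
  fld <- cohort_fields()
  canon <- c("id", "sex", fld$continuous, fld$flags, fld$optional_flags)

  # resolve each canonical field to a source column: explicit mapping first,
  # then a same-named column
  src_of <- function(f) {
    if (f %in% names(codebook$columns)) codebook$columns[[f]]
    else if (f %in% names(data)) f
    else NA_character_
  }
  sources <- vapply(canon, src_of, character(1))
  mapped_missing <- canon[!is.na(sources) & !(sources %in% names(data))]
  if (length(mapped_missing)) {
    stop("codebook maps field(s) to column(s) absent from the file: ",
         paste(sprintf("%s -> %s", mapped_missing, sources[mapped_missing]),
               collapse = ", "), call. = FALSE)
  }
  absent_required <- intersect(fld$required, canon[is.na(sources)])
  if (length(absent_required)) {
    stop("required column(s) missing (no mapping and no same-named column): ",
         paste(absent_required, collapse = ", "), call. = FALSE)
  }

  n <- nrow(data)
  if (n == 0L) stop("cohort file has no data rows", call. = FALSE)
  problems <- list()
  note <- function(row, id, field, value, problem) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      row = row, id = id, field = field,
      value = as.character(value), problem = problem
    )
  }

  out <- tibble::tibble(.rows = n)

  # id: verbatim if present, else generated; must be unique
  if (!is.na(sources[["id"]])) {
    out$id <- as.character(data[[sources[["id"]]]])
    if (anyDuplicated(out$id)) {
      stop("participant ids are not unique", call. = FALSE)
    }
  } else {
    out$id <- sprintf("P%04d", seq_len(n))
  }

  # sex: mapped through the codebook's value encoding
  sex_raw <- as.character(data[[sources[["sex"]]]])
  sex_map <- codebook$sex_values
  out$sex <- unname(sex_map[sex_raw])
  bad_sex <- which(!is.na(sex_raw) & is.na(out$sex))
  for (i in bad_sex) note(i, out$id[i], "sex", sex_raw[i],
                          "unrecognized sex encoding")

  for (f in fld$continuous) {
    if (is.na(sources[[f]])) { out[[f]] <- NA_real_; next }
    v_raw <- data[[sources[[f]]]]
    v <- suppressWarnings(as.numeric(as.character(v_raw)))
    bad <- which(!is.na(v_raw) & trimws(as.character(v_raw)) != "" & is.na(v))
    for (i in bad) note(i, out$id[i], f, v_raw[i], "not numeric")
    if (f %in% names(codebook$units) && codebook$units[[f]] == "mmol/L") {
      v <- v * .unit_factors[[f]]
    }
    neg <- which(!is.na(v) & v <= 0 & f != "age_years")
    neg <- c(neg, which(!is.na(v) & v < 0 & f == "age_years"))
    for (i in neg) {
      note(i, out$id[i], f, v[i], "non-positive measurement")
      v[i] <- NA_real_
    }
    out[[f]] <- v
  }

  to_logical <- function(v_raw, f) {
    s <- tolower(trimws(as.character(v_raw)))
    v <- rep(NA, length(s))
    v[s %in% tolower(codebook$true_values)] <- TRUE
    v[s %in% tolower(codebook$false_values)] <- FALSE
    bad <- which(!is.na(v_raw) & s != "" & s != "na" & is.na(v))
    for (i in bad) note(i, out$id[i], f, v_raw[i], "not interpretable as logical")
    v
  }
  for (f in c(fld$flags, fld$optional_flags)) {
    out[[f]] <- if (is.na(sources[[f]])) NA else to_logical(data[[sources[[f]]]], f)
  }

  # invariant: polycystic ovary syndrome only in females
  bad_pcos <- which(!is.na(out$pcos) & out$pcos &
                      !is.na(out$sex) & out$sex == "male")
  for (i in bad_pcos) {
    note(i, out$id[i], "pcos", TRUE, "pcos set for a male record; cleared to NA")
    out$pcos[i] <- NA
  }

  out$age_over_40 <- !is.na(out$age_years) & out$age_years > 40

  problems <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(row = integer(), id = character(), field = character(),
                   value = character(), problem = character())
  attr(out, "provenance") <- provenance
  attr(out, "problems") <- problems
  out
}

#' Write a cohort back to CSV in the canonical layout
#'
#' @param cohort A canonical cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Row-level validation problems recorded at ingest
#' @param cohort A cohort returned by [read_cohort()]/[canonicalize_cohort()].
#' @return A tibble of row-level problems (possibly empty).
#' @export
ingest_problems <- function(cohort) {
  p <- attr(cohort, "problems")
  if (is.null(p)) {
    tibble::tibble(row = integer(), id = character(), field = character(),
                   value = character(), problem = character())
  } else p
}

#' Which required fields is each record missing?
#'
#' A record is classifiable under all six definitions only when sex and the
#' five component inputs (waist circumference, the blood-pressure pair,
#' fasting glucose, triglycerides, HDL) plus the diabetes and hypertension
#' treatment/diagnosis flags are all present. Optional risk-history flags
#' (family history, gestational diabetes) are not required: when unknown they
#' simply never satisfy an insulin-resistance risk indicator.
#'
#' @param cohort A canonical cohort tibble.
#' @return A tibble `id`, `n_missing`, `missing_fields` (comma-separated).
#' @export
missing_required_fields <- function(cohort) {
  req <- cohort_fields()$required
  miss <- purrr::map(req, ~ is.na(cohort[[.x]]))
  names(miss) <- req
  miss_mat <- do.call(cbind, miss)
  tibble::tibble(
    id = cohort$id,
    n_missing = rowSums(miss_mat),
    missing_fields = apply(miss_mat, 1L, function(r)
      paste(req[r], collapse = ","))
  )
}

#' Split a cohort into classifiable records and an exclusion report
#'
#' Mirrors the study-style handling of incomplete records: participants whose
#' database rows lack any field required by the six definitions are excluded
#' from classification (never imputed) and accounted for in a per-record
#' exclusion report, so that kept + excluded always reconciles with the input.
#'
#' @param cohort A canonical cohort tibble.
#' @return A list with `cohort` (classifiable rows, same column layout) and
#'   `exclusions` (tibble `id`, `missing_fields` for the dropped rows).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 8, seed = 1))
#' coh$glucose_mgdl[2] <- NA
#' filter_classifiable(coh)$exclusions
filter_classifiable <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  mm <- missing_required_fields(cohort)
  keep <- mm$n_missing == 0L
  list(
    cohort = cohort[keep, , drop = FALSE],
    exclusions = tibble::tibble(
      id = mm$id[!keep],
      missing_fields = mm$missing_fields[!keep]
    )
  )
}
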