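#' Canonical participant fields
#'
#' The canonical column layout used throughout the package. Continuous
#' measures are stored in fixed clinical units -- mg/dL for fasting glucose,
#' triglycerides and HDL cholesterol, mmHg for blood pressure, cm for waist
#' circumference, kg/m^2 for BMI -- because every published cutoff is printed
#' in those units; conversions happen once, at ingest.
#'
#' @return A named list with character vectors `continuous`, `flags`,
#'   `optional_flags` and `required` (the fields a record must carry to be
#'   classifiable under all six definitions).
#' @export
#' @examples
#' cohort_fields()$required
cohort_fields <- function() {
  continuous <- c(
    "age_years", "waist_cm", "bmi", "sbp_mmhg", "dbp_mmhg",
    "glucose_mgdl", "tg_mgdl", "hdl_mgdl"
  )
  flags <- c(
    "dm_diagnosis", "dm_treatment", "sah_treatment", "sah_diagnosis",
    "cvd", "pcos", "nafld", "acanthosis", "sedentary", "nonwhite"
  )
  optional_flags <- c("family_history", "gestational_dm")
  list(
    continuous = continuous,
    flags = flags,
    optional_flags = optional_flags,
    # sex + the five component inputs (waist, BP pair, glucose, TG, HDL)
    # + treatment/diagnosis flags consumed by the substitution rules
    required = c(
      "sex", "waist_cm", "sbp_mmhg", "dbp_mmhg",
      "glucose_mgdl", "tg_mgdl", "hdl_mgdl",
      "dm_diagnosis", "dm_treatment", "sah_treatment"
    )
  )
}

#' Build a codebook mapping source columns to canonical fields
#'
#' A codebook declares how a deposited spreadsheet/CSV maps onto the canonical
#' layout: which source column holds each canonical field, how sex is encoded,
#' and which unit each laboratory column uses. The supplementary-data layout
#' of a study is defined by its own codebook document, so the mapping is
#' user-supplied rather than hard-coded.
#'
#' @param columns Named character vector `canonical_field = "source column"`.
#'   Canonical fields not listed are taken verbatim when a column of that name
#'   exists, otherwise treated as absent.
#' @param sex_values Named character vector mapping source encodings to
#'   `"female"`/`"male"`, e.g. `c(F = "female", M = "male")`.
#' @param true_values,false_values Character vectors of source encodings
#'   interpreted as logical TRUE/FALSE for flag columns.
#' @param units Named character vector over `glucose_mgdl`, `tg_mgdl`,
#'   `hdl_mgdl` with values `"mg/dL"` (default) or `"mmol/L"`. mmol/L columns
#'   are converted at ingest (glucose x18.016, TG x88.57, HDL x38.67).
#' @return An object of class `mets_codebook`.
#' @export
#' @examples
#' cb <- mets_codebook(columns = c(waist_cm = "wc", sex = "gender"),
#'                     sex_values = c(`1` = "female", `2` = "male"))
mets_codebook <- function(columns = character(),
                          sex_values = c(female = "female", male = "male",
                                         f = "female", m = "male",
                                         F = "female", M = "male"),
                          true_values = c("1", "true", "TRUE", "yes", "y"),
                          false_values = c("0", "false", "FALSE", "no", "n"),
                          units = c(glucose_mgdl = "mg/dL",
                                    tg_mgdl = "mg/dL",
                                    hdl_mgdl = "mg/dL")) {
  columns <- unlist(columns)
  if (length(columns) && (is.null(names(columns)) || any(names(columns) == ""))) {
    stop("`columns` must be a named vector: canonical_field = \"source column\"",
         call. = FALSE)
  }
  if (anyDuplicated(names(columns))) {
    dup <- unique(names(columns)[duplicated(names(columns))])
    stop("canonical field(s) mapped to more than one source column: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  known <- c("id", "sex", cohort_fields()$continuous, cohort_fields()$flags,
             cohort_fields()$optional_flags)
  unknown <- setdiff(names(columns), known)
  if (length(unknown)) {
    stop("unknown canonical field(s) in codebook: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_units <- setdiff(units, c("mg/dL", "mmol/L"))
  if (length(bad_units)) {
    stop("unsupported unit(s): ", paste(bad_units, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(columns = columns, sex_values = sex_values,
         true_values = true_values, false_values = false_values,
         units = units),
    class = "mets_codebook"
  )
}

#' Default codebook (identity column mapping, mg/dL units)
#' @return A `mets_codebook`.
#' @export
default_codebook <- function() mets_codebook()

#' @export
print.mets_codebook <- function(x, ...) {
  cat("<mets_codebook>\n")
  if (length(x$columns)) {
    cat("  column mapping:\n")
    for (i in seq_along(x$columns)) {
      cat("    ", names(x$columns)[i], " <- ", x$columns[[i]], "\n", sep = "")
    }
  } else {
    cat("  identity column mapping\n")
  }
  mm <- names(x$units)[x$units == "mmol/L"]
  cat("  units: ", if (length(mm)) paste(mm, "in mmol/L") else "all mg/dL",
      "\n", sep = "")
  invisible(x)
}

# mmol/L -> mg/dL molar conversion factors
.unit_factors <- c(glucose_mgdl = 18.016, tg_mgdl = 88.57, hdl_mgdl = 38.67)
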