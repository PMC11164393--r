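#' Construct a MetS criterion definition
#'
#' A criterion is a declarative rule set: component predicates with
#' sex-specific cutoffs and comparators, treatment/diagnosis substitution
#' flags that force a component positive, an optional mandatory gate, and the
#' minimum number of positive (non-gate) components required for diagnosis.
#'
#' @param name Short identifier, e.g. `"IDF"`.
#' @param label Human-readable label.
#' @param predicates A tibble with columns `component` (one of `waist`,
#'   `triglycerides`, `hdl`, `blood_pressure`, `glucose`), `comparator`
#'   (`"ge"`, `"gt"` or `"lt"`), `cutoff_female`, `cutoff_male`, and for the
#'   blood-pressure row `dbp_cutoff` (the predicate is SBP vs cutoff OR DBP vs
#'   `dbp_cutoff`), plus a list-column `substitutions` of record flags that
#'   force positivity (e.g. `"sah_treatment"`).
#' @param mandatory `"none"`, a component name that must be positive before
#'   the remaining components are counted (e.g. `"waist"`), or one of the
#'   special gates `"ir_risk"` (insulin-resistance risk indicator list) and
#'   `"hyperglycemia_proxy"` (fasting glucose at `gate_glucose_cutoff` or
#'   diabetes diagnosis/treatment -- the operational stand-in for an
#'   insulin-resistance requirement in cohorts without insulin assays).
#' @param min_components Minimum count of positive non-gate components.
#' @param gate_glucose_cutoff Cutoff (mg/dL) for the hyperglycemia proxy gate.
#' @return An object of class `mets_criterion`.
#' @seealso [mets_criteria()] for the built-in registry.
#' @export
criterion_definition <- function(name, label = name, predicates,
                                 mandatory = "none", min_components,
                                 gate_glucose_cutoff = 110) {
  stopifnot(is.character(name), length(name) == 1L)
  predicates <- tibble::as_tibble(predicates)
  needed <- c("component", "comparator", "cutoff_female", "cutoff_male")
  if (!all(needed %in% names(predicates))) {
    stop("predicates must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"dbp_cutoff" %in% names(predicates)) predicates$dbp_cutoff <- NA_real_
  if (!"substitutions" %in% names(predicates)) {
    predicates$substitutions <- vector("list", nrow(predicates))
  }
  ok_comp <- c("waist", "triglycerides", "hdl", "blood_pressure", "glucose")
  if (!all(predicates$component %in% ok_comp)) {
    stop("unknown component(s): ",
         paste(setdiff(predicates$component, ok_comp), collapse = ", "),
         call. = FALSE)
  }
  if (!all(predicates$comparator %in% c("ge", "gt", "lt"))) {
    stop("comparator must be one of ge, gt, lt", call. = FALSE)
  }
  # HDL is the only risk factor where LOW values are adverse
  if (any(predicates$component == "hdl" & predicates$comparator != "lt") ||
      any(predicates$component != "hdl" & predicates$comparator == "lt")) {
    stop("comparator direction fixed per component: hdl uses lt, others ge/gt",
         call. = FALSE)
  }
  counted <- setdiff(predicates$component, mandatory)
  if (min_components > length(counted)) {
    stop("min_components exceeds the number of countable components",
         call. = FALSE)
  }
  gates <- c("none", "ir_risk", "hyperglycemia_proxy", ok_comp)
  if (!mandatory %in% gates) stop("invalid mandatory gate: ", mandatory,
                                  call. = FALSE)
  if (mandatory %in% ok_comp && !mandatory %in% predicates$component) {
    stop("mandatory component ", mandatory, " has no predicate", call. = FALSE)
  }
  structure(
    list(name = name, label = label, predicates = predicates,
         mandatory = mandatory, min_components = as.integer(min_components),
         gate_glucose_cutoff = gate_glucose_cutoff),
    class = "mets_criterion"
  )
}

#' @export
print.mets_criterion <- function(x, ...) {
  cmp <- c(ge = ">=", gt = ">", lt = "<")
  cat("<mets_criterion> ", x$label, "\n", sep = "")
  gate <- switch(x$mandatory,
    none = "none",
    ir_risk = "insulin-resistance risk indicator (any of the listed factors)",
    hyperglycemia_proxy = sprintf(
      "fasting glucose >= %g mg/dL or DM diagnosis/treatment",
      x$gate_glucose_cutoff),
    paste0("component `", x$mandatory, "` positive"))
  cat("  mandatory gate: ", gate, "\n", sep = "")
  cat("  requires >= ", x$min_components, " of:\n", sep = "")
  for (i in seq_len(nrow(x$predicates))) {
    p <- x$predicates[i, ]
    if (p$component == x$mandatory) next
    lim <- if (p$cutoff_female == p$cutoff_male) {
      sprintf("%s %g", cmp[[p$comparator]], p$cutoff_female)
    } else {
      sprintf("%s %g (M) / %g (F)", cmp[[p$comparator]], p$cutoff_male,
              p$cutoff_female)
    }
    if (p$component == "blood_pressure") {
      lim <- sprintf("%s/%g", lim, p$dbp_cutoff)
    }
    sub <- p$substitutions[[1]]
    cat("    ", format(p$component, width = 14), lim,
        if (length(sub)) paste0("  [or ", paste(sub, collapse = "/"), "]") else "",
        "\n", sep = "")
  }
  invisible(x)
}

pred_row <- function(component, comparator, f, m, dbp = NA_real_,
                     substitutions = character()) {
  tibble::tibble(component = component, comparator = comparator,
                 cutoff_female = f, cutoff_male = m, dbp_cutoff = dbp,
                 substitutions = list(substitutions))
}

#' Built-in registry of the six MetS definitions
#'
#' Returns the six rule sets in their published form (all laboratory cutoffs
#' in mg/dL, blood pressure in mmHg, waist circumference in cm):
#'
#' * `IDF_AHA_NHLBI` (harmonized 2009, the gold standard): any 3 of
#'   \{WC >= 90 (M) / 80 (F); TG >= 150; HDL < 40 (M) / 50 (F);
#'   BP >= 130/85 or hypertension treatment; glucose >= 100 or diabetes
#'   diagnosis/treatment\}.
#' * `NCEP_ATPIII`: same five components with WC > 102 (M) / 88 (F).
#' * `BARBOSA2006`: NCEP-ATPIII rules with Brazilian waist cutoffs
#'   WC > 88 (M) / 84 (F).
#' * `IDF`: central obesity mandatory (WC >= 90 (M) / 80 (F)) plus any 2 of
#'   the remaining four harmonized components.
#' * `EGIR`: mandatory insulin-resistance gate -- operationalized, absent
#'   insulin assays, as fasting glucose >= 110 mg/dL or diabetes
#'   diagnosis/treatment (`egir_glucose_cutoff`) -- plus any 2 of
#'   \{WC >= 94 (M) / 80 (F); TG >= 150; HDL < 39 (both sexes);
#'   BP >= 140/90 or hypertension treatment\}.
#' * `AACE`: mandatory high-risk-of-insulin-resistance gate (at least one of:
#'   cardiovascular disease, hypertension diagnosis, polycystic ovary
#'   syndrome, non-alcoholic fatty liver disease, Acanthosis nigricans,
#'   family history of T2DM/hypertension/CVD, gestational diabetes or glucose
#'   intolerance history, non-white ethnicity, sedentary lifestyle, age > 40,
#'   BMI >= 25, or WC > 94 (M) / 80 (F)) plus any 2 of \{TG >= 150;
#'   HDL < 40 (M) / 50 (F); BP >= 130/85\}. By default the AACE rule carries
#'   no glucose component (no oral glucose tolerance testing); set
#'   `aace_glucose = TRUE` to add the canonical impaired-fasting-glucose band
#'   (110--125 mg/dL) as a counted component.
#'
#' Treatment/diagnosis substitutions are applied to the blood-pressure and
#' glucose components of every definition that includes them: hypertension
#' treatment forces the blood-pressure component positive, and a prior
#' diabetes diagnosis or treatment forces the glucose component positive.
#' Lipid-lowering treatment is deliberately not a substitution (cohorts of
#' this design do not record it).
#'
#' @param names Which definitions to return (default all six, gold standard
#'   first).
#' @param egir_glucose_cutoff Glucose cutoff (mg/dL) of the EGIR
#'   insulin-resistance proxy gate.
#' @param aace_glucose Add the 110--125 mg/dL glucose band to AACE.
#' @return A named list of [criterion_definition()] objects.
#' @export
#' @examples
#' names(mets_criteria())
#' mets_criteria("EGIR")[[1]]
mets_criteria <- function(names = c("IDF_AHA_NHLBI", "IDF", "NCEP_ATPIII",
                                    "BARBOSA2006", "EGIR", "AACE"),
                          egir_glucose_cutoff = 110,
                          aace_glucose = FALSE) {
  harmonized_tail <- dplyr::bind_rows(
    pred_row("triglycerides", "ge", 150, 150),
    pred_row("hdl", "lt", 50, 40),
    pred_row("blood_pressure", "ge", 130, 130, dbp = 85,
             substitutions = "sah_treatment"),
    pred_row("glucose", "ge", 100, 100,
             substitutions = c("dm_diagnosis", "dm_treatment"))
  )
  aace_preds <- dplyr::bind_rows(
    pred_row("triglycerides", "ge", 150, 150),
    pred_row("hdl", "lt", 50, 40),
    pred_row("blood_pressure", "ge", 130, 130, dbp = 85,
             substitutions = "sah_treatment")
  )
  if (aace_glucose) {
    # canonical AACE counts impaired fasting glucose (110-125), not diabetes
    aace_preds <- dplyr::bind_rows(
      aace_preds, pred_row("glucose", "ge", 110, 110))
  }
  registry <- list(
    IDF_AHA_NHLBI = criterion_definition(
      "IDF_AHA_NHLBI", "IDF/AHA/NHLBI harmonized (2009)",
      dplyr::bind_rows(pred_row("waist", "ge", 80, 90), harmonized_tail),
      mandatory = "none", min_components = 3),
    NCEP_ATPIII = criterion_definition(
      "NCEP_ATPIII", "NCEP ATP III",
      dplyr::bind_rows(pred_row("waist", "gt", 88, 102), harmonized_tail),
      mandatory = "none", min_components = 3),
    BARBOSA2006 = criterion_definition(
      "BARBOSA2006", "Barbosa et al. (2006)",
      dplyr::bind_rows(pred_row("waist", "gt", 84, 88), harmonized_tail),
      mandatory = "none", min_components = 3),
    IDF = criterion_definition(
      "IDF", "IDF (2005)",
      dplyr::bind_rows(pred_row("waist", "ge", 80, 90), harmonized_tail),
      mandatory = "waist", min_components = 2),
    EGIR = criterion_definition(
      "EGIR", "EGIR",
      dplyr::bind_rows(
        pred_row("waist", "ge", 80, 94),
        pred_row("triglycerides", "ge", 150, 150),
        pred_row("hdl", "lt", 39, 39),
        pred_row("blood_pressure", "ge", 140, 140, dbp = 90,
                 substitutions = "sah_treatment")),
      mandatory = "hyperglycemia_proxy", min_components = 2,
      gate_glucose_cutoff = egir_glucose_cutoff),
    AACE = criterion_definition(
      "AACE", "AACE", aace_preds,
      mandatory = "ir_risk", min_components = 2)
  )
  unknown <- setdiff(names, names(registry))
  if (length(unknown)) {
    stop("unknown criterion name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  registry[names]
}

# vectorized comparator; NA-safe (NA input -> NA output)
.compare <- function(x, comparator, cutoff) {
  switch(comparator, ge = x >= cutoff, gt = x > cutoff, lt = x < cutoff)
}

# flag vector with NA treated as FALSE (unknown never satisfies a rule)
.flag <- function(cohort, name) {
  v <- cohort[[name]]
  if (is.null(v)) return(rep(FALSE, nrow(cohort)))
  !is.na(v) & v
}

# AACE high-risk-of-insulin-resistance indicator list
.ir_risk_gate <- function(cohort) {
  bmi_hi <- !is.na(cohort$bmi) & cohort$bmi >= 25
  wc_cut <- ifelse(cohort$sex == "male", 94, 80)
  wc_hi <- !is.na(cohort$waist_cm) & cohort$waist_cm > wc_cut
  .flag(cohort, "cvd") | .flag(cohort, "sah_diagnosis") |
    .flag(cohort, "pcos") | .flag(cohort, "nafld") |
    .flag(cohort, "acanthosis") | .flag(cohort, "family_history") |
    .flag(cohort, "gestational_dm") | .flag(cohort, "nonwhite") |
    .flag(cohort, "sedentary") |
    (!is.na(cohort$age_years) & cohort$age_years > 40) |
    bmi_hi | wc_hi
}

#' Evaluate the component predicates of one criterion over a cohort
#'
#' Each component is compared with the sex-appropriate cutoff using the
#' definition's printed comparator (strict `>` vs `>=` matters at boundary
#' values), after applying treatment/diagnosis substitutions. The
#' blood-pressure predicate is positive when either the systolic or the
#' diastolic reading crosses its cutoff.
#'
#' @param cohort A classifiable canonical cohort tibble (see
#'   [filter_classifiable()]).
#' @param criterion A single [criterion_definition()].
#' @return A tibble with `id`, one logical column per component of the
#'   definition, `mandatory_gate` (TRUE when the definition has no gate),
#'   `n_positive` (count of positive non-gate components) and `mets` (the
#'   final classification).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 5, seed = 42))
#' evaluate_components(coh, mets_criteria("IDF")[[1]])
evaluate_components <- function(cohort, criterion) {
  stopifnot(inherits(criterion, "mets_criterion"))
  mm <- missing_required_fields(cohort)
  if (any(mm$n_missing > 0L)) {
    bad <- mm[mm$n_missing > 0L, ]
    stop("non-classifiable record(s): ",
         paste(sprintf("%s (missing %s)", bad$id, bad$missing_fields),
               collapse = "; "), call. = FALSE)
  }
  p <- criterion$predicates
  is_male <- cohort$sex == "male"
  comp <- list()
  for (i in seq_len(nrow(p))) {
    row <- p[i, ]
    cut <- ifelse(is_male, row$cutoff_male, row$cutoff_female)
    val <- switch(row$component,
      waist = .compare(cohort$waist_cm, row$comparator, cut),
      triglycerides = .compare(cohort$tg_mgdl, row$comparator, cut),
      hdl = .compare(cohort$hdl_mgdl, row$comparator, cut),
      glucose = .compare(cohort$glucose_mgdl, row$comparator, cut),
      blood_pressure = .compare(cohort$sbp_mmhg, row$comparator, cut) |
        .compare(cohort$dbp_mmhg, row$comparator, row$dbp_cutoff)
    )
    for (s in row$substitutions[[1]]) val <- val | .flag(cohort, s)
    comp[[row$component]] <- val
  }
  gate <- switch(criterion$mandatory,
    none = rep(TRUE, nrow(cohort)),
    ir_risk = .ir_risk_gate(cohort),
    hyperglycemia_proxy =
      (cohort$glucose_mgdl >= criterion$gate_glucose_cutoff) |
        .flag(cohort, "dm_diagnosis") | .flag(cohort, "dm_treatment"),
    comp[[criterion$mandatory]]
  )
  counted <- setdiff(names(comp), criterion$mandatory)
  n_pos <- Reduce(`+`, comp[counted])
  out <- tibble::tibble(id = cohort$id, criterion = criterion$name)
  for (nm in names(comp)) out[[nm]] <- comp[[nm]]
  out$mandatory_gate <- gate
  out$n_positive <- as.integer(n_pos)
  out$mets <- gate & n_pos >= criterion$min_components
  out
}

#' Classify a cohort under one or several MetS definitions
#'
#' @param cohort A classifiable canonical cohort tibble.
#' @param criteria A list of [criterion_definition()]s (default: all six
#'   built-ins, gold standard first). A single criterion is also accepted.
#' @return A tibble with `id`, `sex` and one logical column per criterion, in
#'   the input criteria order.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 20, seed = 7))
#' labels <- classify_cohort(coh)
#' colSums(labels[, -(1:2)])
classify_cohort <- function(cohort, criteria = mets_criteria()) {
  if (inherits(criteria, "mets_criterion")) criteria <- list(criteria)
  out <- tibble::tibble(id = cohort$id, sex = cohort$sex)
  for (cr in criteria) {
    out[[cr$name]] <- evaluate_components(cohort, cr)$mets
  }
  out
}

#' Prevalence of a binary label with an exact 95% confidence interval
#'
#' @param labels Logical vector (no NAs).
#' @param stratum Optional logical mask selecting a subset.
#' @param level Confidence level.
#' @return A one-row tibble: `n`, `positives`, `estimate` (proportion),
#'   `conf_low`, `conf_high` (Clopper-Pearson exact bounds).
#' @export
#' @examples
#' prevalence(c(rep(TRUE, 347), rep(FALSE, 764)))
prevalence <- function(labels, stratum = NULL, level = 0.95) {
  if (!is.null(stratum)) labels <- labels[stratum]
  if (length(labels) == 0L) stop("empty stratum", call. = FALSE)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  k <- sum(labels)
  n <- length(labels)
  ci <- exact_ci(k, n, level = level)
  tibble::tibble(n = n, positives = k, estimate = k / n,
                 conf_low = ci[[1]], conf_high = ci[[2]])
}

#' Serialize a criteria registry to human-readable JSON
#'
#' Lets users audit or modify cutoffs outside R; the JSON round-trips through
#' [criteria_from_json()].
#'
#' @param criteria A list of [criterion_definition()]s.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
criteria_to_json <- function(criteria, path = NULL) {
  if (inherits(criteria, "mets_criterion")) criteria <- list(criteria)
  payload <- purrr::map(criteria, function(cr) {
    preds <- cr$predicates
    preds$substitutions <- purrr::map(preds$substitutions, as.character)
    list(name = cr$name, label = cr$label, mandatory = cr$mandatory,
         min_components = cr$min_components,
         gate_glucose_cutoff = cr$gate_glucose_cutoff,
         predicates = preds)
  })
  names(payload) <- purrr::map_chr(criteria, "name")
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' Read a criteria registry back from JSON
#' @param path Path to a JSON file written by [criteria_to_json()].
#' @return A named list of [criterion_definition()]s.
#' @export
criteria_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  out <- purrr::map(payload, function(cr) {
    preds <- tibble::as_tibble(cr$predicates)
    if (!is.list(preds$substitutions)) {
      preds$substitutions <- as.list(preds$substitutions)
    }
    preds$substitutions <- purrr::map(preds$substitutions, as.character)
    criterion_definition(cr$name, cr$label, preds, mandatory = cr$mandatory,
                         min_components = cr$min_components,
                         gate_glucose_cutoff = cr$gate_glucose_cutoff %||% 110)
  })
  names(out) <- purrr::map_chr(out, "name")
  out
}
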