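# In-code fixtures: a fully negative baseline record whose fields can be
# pushed over any cutoff one at a time.

make_cohort <- function(n = 1, ...) {
  base <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    sex = "female",
    age_years = 30,
    waist_cm = 70, bmi = 22,
    sbp_mmhg = 110, dbp_mmhg = 70,
    glucose_mgdl = 85, tg_mgdl = 100, hdl_mgdl = 60,
    dm_diagnosis = FALSE, dm_treatment = FALSE,
    sah_treatment = FALSE, sah_diagnosis = FALSE,
    cvd = FALSE, pcos = FALSE, nafld = FALSE, acanthosis = FALSE,
    sedentary = FALSE, nonwhite = FALSE,
    family_history = NA, gestational_dm = NA,
    age_over_40 = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# one record per call, convenient for single-record classification checks
make_record <- function(...) make_cohort(n = 1, ...)

crit <- function(name) mets_criteria(name)[[1]]

# the five 2x2 tables exactly recoverable from the published summary counts
published_tables <- function() {
  list(
    IDF = confusion_table(330, 0, 17, 764),
    BARBOSA2006 = confusion_table(322, 1, 25, 763),
    NCEP_ATPIII = confusion_table(290, 0, 57, 764),
    EGIR = confusion_table(52, 0, 295, 764),
    AACE = confusion_table(144, 4, 203, 760)
  )
}

get_metric <- function(report, which) report$estimate[report$metric == which]
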