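test_that("waist cutoffs honor the printed comparators at the boundary", {
  cases <- list(
    # criterion, sex, wc, expected waist-component status
    list("IDF_AHA_NHLBI", "female", 80.0, TRUE),   # >= is inclusive
    list("IDF_AHA_NHLBI", "female", 79.999, FALSE),
    list("IDF_AHA_NHLBI", "male", 90.0, TRUE),
    list("IDF", "female", 80.0, TRUE),
    list("EGIR", "female", 80.0, TRUE),
    list("EGIR", "male", 94.0, TRUE),
    list("EGIR", "male", 93.999, FALSE),
    list("NCEP_ATPIII", "male", 102.0, FALSE),     # > is strict
    list("NCEP_ATPIII", "male", 102.001, TRUE),
    list("NCEP_ATPIII", "female", 88.0, FALSE),
    list("BARBOSA2006", "male", 88.0, FALSE),
    list("BARBOSA2006", "male", 88.001, TRUE),
    list("BARBOSA2006", "female", 84.0, FALSE),
    list("BARBOSA2006", "female", 84.001, TRUE)
  )
  for (cs in cases) {
    rec <- make_record(sex = cs[[2]], waist_cm = cs[[3]])
    ev <- evaluate_components(rec, crit(cs[[1]]))
    expect_equal(ev$waist, cs[[4]],
                 info = sprintf("%s %s wc=%g", cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("lab and blood-pressure cutoffs are sex- and criterion-specific", {
  # HDL: < comparator, sex-specific except EGIR's shared 39
  ev <- evaluate_components(make_record(sex = "female", hdl_mgdl = 50),
                            crit("IDF_AHA_NHLBI"))
  expect_false(ev$hdl)   # 50 is not < 50
  ev <- evaluate_components(make_record(sex = "female", hdl_mgdl = 49.9),
                            crit("IDF_AHA_NHLBI"))
  expect_true(ev$hdl)
  ev <- evaluate_components(make_record(sex = "male", hdl_mgdl = 39.9),
                            crit("IDF_AHA_NHLBI"))
  expect_true(ev$hdl)
  for (sx in c("female", "male")) {
    ev <- evaluate_components(make_record(sex = sx, hdl_mgdl = 38.9),
                              crit("EGIR"))
    expect_true(ev$hdl, info = sx)
    ev <- evaluate_components(make_record(sex = sx, hdl_mgdl = 39),
                              crit("EGIR"))
    expect_false(ev$hdl, info = sx)
  }
  # TG >= 150 everywhere
  expect_true(evaluate_components(make_record(tg_mgdl = 150),
                                  crit("AACE"))$triglycerides)
  # BP: either arm crosses -> positive; EGIR uses 140/90
  expect_true(evaluate_components(make_record(sbp_mmhg = 130),
                                  crit("IDF_AHA_NHLBI"))$blood_pressure)
  expect_true(evaluate_components(make_record(dbp_mmhg = 85),
                                  crit("IDF_AHA_NHLBI"))$blood_pressure)
  expect_false(evaluate_components(make_record(sbp_mmhg = 135),
                                   crit("EGIR"))$blood_pressure)
  expect_true(evaluate_components(make_record(sbp_mmhg = 140),
                                  crit("EGIR"))$blood_pressure)
  expect_true(evaluate_components(make_record(dbp_mmhg = 90),
                                  crit("EGIR"))$blood_pressure)
  # glucose >= 100 (harmonized family)
  expect_true(evaluate_components(make_record(glucose_mgdl = 100),
                                  crit("NCEP_ATPIII"))$glucose)
  expect_false(evaluate_components(make_record(glucose_mgdl = 99.9),
                                   crit("NCEP_ATPIII"))$glucose)
})

test_that("treatment/diagnosis substitutions force component positivity", {
  rec <- make_record(glucose_mgdl = 90, dm_treatment = TRUE)
  expect_true(evaluate_components(rec, crit("IDF_AHA_NHLBI"))$glucose)
  rec <- make_record(glucose_mgdl = 90, dm_diagnosis = TRUE)
  expect_true(evaluate_components(rec, crit("IDF"))$glucose)
  rec <- make_record(sbp_mmhg = 110, dbp_mmhg = 70, sah_treatment = TRUE)
  for (nm in c("IDF_AHA_NHLBI", "NCEP_ATPIII", "BARBOSA2006", "IDF",
               "EGIR", "AACE")) {
    expect_true(evaluate_components(rec, crit(nm))$blood_pressure, info = nm)
  }
})

test_that("classification follows mandatory gates and component-count thresholds", {
  # exactly 3 of 5 harmonized components -> positive under the gold standard
  rec3 <- make_record(tg_mgdl = 160, hdl_mgdl = 45, sbp_mmhg = 135)
  lab <- classify_cohort(rec3)
  expect_true(lab$IDF_AHA_NHLBI)
  # 4 positive but waist negative: harmonized positive, IDF negative (gate)
  rec4 <- make_record(tg_mgdl = 160, hdl_mgdl = 45, sbp_mmhg = 135,
                      glucose_mgdl = 105, waist_cm = 70)
  lab <- classify_cohort(rec4)
  expect_true(lab$IDF_AHA_NHLBI)
  expect_false(lab$IDF)
  # EGIR gate fails at glucose 105 even with all four components positive
  rec_egir <- make_record(glucose_mgdl = 105, waist_cm = 95, tg_mgdl = 160,
                          hdl_mgdl = 35, sbp_mmhg = 145, sex = "male")
  ev <- evaluate_components(rec_egir, crit("EGIR"))
  expect_equal(ev$n_positive, 4L)
  expect_false(ev$mandatory_gate)
  expect_false(ev$mets)
  # gate opens at 110
  rec_egir$glucose_mgdl <- 110
  expect_true(evaluate_components(rec_egir, crit("EGIR"))$mets)
  # AACE: two components but no risk indicator -> negative; any indicator flips
  rec_aace <- make_record(tg_mgdl = 160, hdl_mgdl = 45, bmi = 22,
                          age_years = 30)
  expect_false(classify_cohort(rec_aace, crit("AACE"))$AACE)
  for (flag in c("cvd", "sah_diagnosis", "pcos", "nafld", "acanthosis",
                 "sedentary", "nonwhite")) {
    r <- rec_aace
    r[[flag]] <- TRUE
    expect_true(classify_cohort(r, crit("AACE"))$AACE, info = flag)
  }
  expect_true(classify_cohort(
    make_record(tg_mgdl = 160, hdl_mgdl = 45, age_years = 41),
    crit("AACE"))$AACE)           # age > 40 indicator
  expect_true(classify_cohort(
    make_record(tg_mgdl = 160, hdl_mgdl = 45, bmi = 25),
    crit("AACE"))$AACE)           # BMI >= 25 indicator
  expect_true(classify_cohort(
    make_record(tg_mgdl = 160, hdl_mgdl = 45, waist_cm = 80.5),
    crit("AACE"))$AACE)           # WC > 80 (F) indicator
  # unknown optional history flags never satisfy the gate
  expect_false(classify_cohort(
    make_record(tg_mgdl = 160, hdl_mgdl = 45, family_history = NA),
    crit("AACE"))$AACE)
})

test_that("n_positive counts true components and errors name missing fields", {
  rec <- make_record(tg_mgdl = 160, hdl_mgdl = 45)
  ev <- evaluate_components(rec, crit("IDF_AHA_NHLBI"))
  expect_equal(ev$n_positive,
               sum(ev$waist, ev$triglycerides, ev$hdl, ev$blood_pressure,
                   ev$glucose))
  bad <- make_record(id = "X1")
  bad$hdl_mgdl <- NA
  err <- expect_error(evaluate_components(bad, crit("IDF")))
  expect_match(conditionMessage(err), "X1")
  expect_match(conditionMessage(err), "hdl_mgdl")
})

test_that("classify_cohort is deterministic, ordered, and all-false on a cohort under every cutoff", {
  coh <- make_cohort(4)
  crits <- mets_criteria(c("EGIR", "IDF", "AACE"))
  lab <- classify_cohort(coh, crits)
  expect_equal(names(lab), c("id", "sex", "EGIR", "IDF", "AACE"))
  expect_false(any(as.matrix(lab[, 3:5])))
  lab6 <- classify_cohort(coh)
  expect_equal(dim(lab6), c(4L, 8L))
  expect_false(any(as.matrix(lab6[, -(1:2)])))
})

test_that("monotonicity: worsening any risk measure never flips positive to negative", {
  set.seed(501)
  spec <- cohort_spec(n = 120, seed = 501)
  coh <- simulate_cohort(spec)
  crits <- mets_criteria()
  before <- classify_cohort(coh, crits)
  bumps <- list(
    waist_cm = +5, tg_mgdl = +40, sbp_mmhg = +15, dbp_mmhg = +10,
    glucose_mgdl = +20, hdl_mgdl = -10, bmi = +3
  )
  for (field in names(bumps)) {
    worse <- coh
    worse[[field]] <- pmax(worse[[field]] + bumps[[field]], 1)
    after <- classify_cohort(worse, crits)
    for (nm in names(crits)) {
      expect_false(any(before[[nm]] & !after[[nm]]),
                   info = sprintf("%s after bumping %s", nm, field))
    }
  }
})

test_that("sex symmetry holds for components with shared cutoffs", {
  set.seed(502)
  coh_f <- simulate_cohort(cohort_spec(n = 60, female_fraction = 1,
                                       seed = 502))
  coh_m <- coh_f
  coh_m$sex <- "male"
  coh_m$pcos <- FALSE
  for (nm in c("IDF_AHA_NHLBI", "EGIR")) {
    ev_f <- evaluate_components(coh_f, crit(nm))
    ev_m <- evaluate_components(coh_m, crit(nm))
    expect_equal(ev_f$triglycerides, ev_m$triglycerides, info = nm)
    expect_equal(ev_f$blood_pressure, ev_m$blood_pressure, info = nm)
    if (nm == "IDF_AHA_NHLBI") expect_equal(ev_f$glucose, ev_m$glucose)
    if (nm == "EGIR") expect_equal(ev_f$hdl, ev_m$hdl)  # shared 39 cutoff
  }
})

test_that("Barbosa and NCEP agree when waist clears or misses both cutoff pairs", {
  set.seed(503)
  coh <- simulate_cohort(cohort_spec(n = 400, seed = 503))
  cut_hi <- ifelse(coh$sex == "male", 102, 88)
  cut_lo <- ifelse(coh$sex == "male", 88, 84)
  same_side <- (coh$waist_cm > cut_hi) | (coh$waist_cm <= cut_lo)
  lab <- classify_cohort(coh, mets_criteria(c("NCEP_ATPIII", "BARBOSA2006")))
  expect_true(any(same_side))
  expect_equal(lab$NCEP_ATPIII[same_side], lab$BARBOSA2006[same_side])
})

test_that("every IDF positive has >= 3 harmonized components, hence is harmonized-positive", {
  set.seed(504)
  coh <- simulate_cohort(cohort_spec(n = 800, seed = 504))
  ev_gold <- evaluate_components(coh, crit("IDF_AHA_NHLBI"))
  lab_idf <- classify_cohort(coh, crit("IDF"))$IDF
  expect_true(all(ev_gold$n_positive[lab_idf] >= 3))
  expect_true(all(ev_gold$mets[lab_idf]))   # zero false positives for IDF
})

test_that("prevalence reproduces study-scale proportions with exact CIs", {
  gold <- c(rep(TRUE, 347), rep(FALSE, 1111 - 347))
  p <- prevalence(gold)
  expect_equal(round(100 * p$estimate, 2), 31.23)
  egir <- c(rep(TRUE, 52), rep(FALSE, 1111 - 52))
  expect_equal(round(100 * prevalence(egir)$estimate, 2), 4.68)
  none <- prevalence(rep(FALSE, 50))
  expect_equal(none$estimate, 0)
  expect_equal(none$conf_low, 0)
  expect_error(prevalence(logical(0)), "empty")
  expect_error(prevalence(gold, stratum = rep(FALSE, 1111)), "empty")
})

test_that("criteria registry round-trips through JSON and stays auditable", {
  path <- withr::local_tempfile(fileext = ".json")
  criteria_to_json(mets_criteria(), path)
  back <- criteria_from_json(path)
  expect_equal(names(back), names(mets_criteria()))
  coh <- simulate_cohort(cohort_spec(n = 150, seed = 505))
  expect_equal(as.data.frame(classify_cohort(coh, back)),
               as.data.frame(classify_cohort(coh, mets_criteria())))
})

test_that("criterion constructor enforces structural invariants", {
  pr <- function(component, comparator) {
    tibble::tibble(component = component, comparator = comparator,
                   cutoff_female = 50, cutoff_male = 40)
  }
  expect_error(criterion_definition(
    "X", predicates = pr("hdl", "ge"), min_components = 1),
    "comparator direction")
  expect_error(criterion_definition(
    "X", predicates = pr("triglycerides", "ge"), min_components = 3),
    "min_components")
  expect_error(criterion_definition(
    "X", predicates = pr("triglycerides", "ge"),
    mandatory = "waist", min_components = 1),
    "no predicate")
})
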