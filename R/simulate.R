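#' Specification of a synthetic MetS cohort
#'
#' The stated world of the generator mirrors a PHC nursing-professionals
#' cohort: 87.7% female; per-sex means/SDs of the seven continuous clinical
#' measures; per-sex exceedance targets for the five harmonized component
#' predicates; an exchangeable latent correlation among the five component
#' axes; and flag probabilities, with treatment/diagnosis flags conditional
#' on the corresponding component being positive so the substitution code
#' paths are exercised.
#'
#' Continuous marginals are location-shifted normals: each keeps the stated
#' SD but its mean is moved so that the sex-appropriate harmonized cutoff
#' falls on the target quantile (quantile matching). The published means
#' remain available in `continuous_params` and are used only where no target
#' constrains a measure (BMI, age).
#'
#' @param n Cohort size.
#' @param female_fraction Proportion of females.
#' @param continuous_params Named list `female`/`male`, each a named list of
#'   `c(mean, sd)` over `glucose`, `tg`, `hdl`, `waist`, `bmi`, `sbp`, `dbp`.
#' @param target_marginals Named list `female`/`male`, each a named numeric
#'   vector of exceedance probabilities over `waist`, `tg`, `hdl`, `bp`,
#'   `glucose` (harmonized cutoffs: WC >= 90/80, TG >= 150, HDL < 40/50,
#'   BP >= 130/85, glucose >= 100).
#' @param rho Exchangeable correlation of the five component latents.
#' @param flag_probs Named numeric vector: `treat_given_pos`,
#'   `treat_given_neg` (DM/SAH treatment conditionals), `sah_dx_extra`,
#'   `cvd`, `pcos`, `nafld`, `acanthosis`, `sedentary`, `nonwhite`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n = 100, seed = 1)
#' spec$target_marginals$female
cohort_spec <- function(n = 1111,
                        female_fraction = 0.877,
                        continuous_params = list(
                          female = list(glucose = c(84.48, 18.04),
                                        tg = c(132.41, 55.24),
                                        hdl = c(58.80, 31.30),
                                        waist = c(86.33, 14.11),
                                        bmi = c(26.18, 8.64),
                                        sbp = c(116.58, 15.44),
                                        dbp = c(77.02, 10.61)),
                          male = list(glucose = c(86.19, 16.08),
                                      tg = c(148.17, 67.27),
                                      hdl = c(57.72, 27.02),
                                      waist = c(89.60, 15.71),
                                      bmi = c(27.55, 4.50),
                                      sbp = c(123.70, 14.09),
                                      dbp = c(82.55, 9.41))),
                        target_marginals = list(
                          female = c(waist = 0.6831, tg = 0.3231,
                                     hdl = 0.4697, bp = 0.1641,
                                     glucose = 0.1631),
                          male = c(waist = 0.5221, tg = 0.4118,
                                   hdl = 0.2279, bp = 0.2721,
                                   glucose = 0.1985)),
                        rho = 0.3,
                        flag_probs = c(treat_given_pos = 0.5,
                                       treat_given_neg = 0.02,
                                       sah_dx_extra = 0.03,
                                       cvd = 0.05, pcos = 0.08,
                                       nafld = 0.05, acanthosis = 0.03,
                                       sedentary = 0.4329,
                                       nonwhite = 0.748),
                        seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must be in [0, 1]", call. = FALSE)
  }
  for (sx in c("female", "male")) {
    tm <- target_marginals[[sx]]
    if (any(tm < 0 | tm > 1)) stop("target marginals must be in [0, 1]",
                                   call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 continuous_params = continuous_params,
                 target_marginals = target_marginals, rho = rho,
                 flag_probs = flag_probs, seed = seed),
            class = "cohort_spec")
}

# mean shift so that P(X >= cutoff) = p for X ~ N(mu, sd) ("ge" direction)
.mu_exceed <- function(cutoff, sd, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  cutoff - sd * stats::qnorm(1 - p)
}
# mean shift so that P(X < cutoff) = p ("lt" direction)
.mu_below <- function(cutoff, sd, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  cutoff - sd * stats::qnorm(p)
}

#' Generate a synthetic cohort
#'
#' Draws the five component axes from a Gaussian copula with exchangeable
#' correlation `rho`, maps each axis to a location-shifted normal marginal
#' calibrated so that the harmonized component predicate's exceedance equals
#' the per-sex target, and draws flags per the spec (treatment flags
#' conditional on component positivity). Systolic and diastolic pressure are
#' comonotone transforms of the single blood-pressure latent, so the union
#' predicate SBP >= 130 OR DBP >= 85 calibrates exactly. Deterministic given
#' `spec$seed`. Degenerate targets (0 or 1) are honored by clamping the
#' measure to the appropriate side of the cutoff.
#'
#' @param spec A [cohort_spec()].
#' @return A canonical cohort tibble (see [cohort_fields()]).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 50, seed = 9))
#' mean(coh$sex == "female")
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  is_m <- sex == "male"

  # exchangeable Gaussian copula over the 5 component axes
  w <- stats::rnorm(n)
  z <- sqrt(spec$rho) * matrix(w, n, 5) +
    sqrt(1 - spec$rho) * matrix(stats::rnorm(n * 5), n, 5)
  colnames(z) <- c("waist", "tg", "hdl", "bp", "glucose")
  u <- stats::pnorm(z)

  prm <- function(measure) {
    p <- spec$continuous_params
    list(f = p$female[[measure]], m = p$male[[measure]])
  }
  tgt <- function(axis) {
    ifelse(is_m, spec$target_marginals$male[[axis]],
           spec$target_marginals$female[[axis]])
  }
  # quantile-matched marginal on the "high is positive" axes
  gen_exceed <- function(axis, measure, cutoff_f, cutoff_m, uu = u[, axis]) {
    pp <- prm(measure)
    sd <- ifelse(is_m, pp$m[2], pp$f[2])
    cutoff <- ifelse(is_m, cutoff_m, cutoff_f)
    p <- tgt(axis)
    v <- .mu_exceed(cutoff, sd, p) + sd * stats::qnorm(uu)
    v <- ifelse(p <= 0, pmin(v, cutoff - 1e-6),
                ifelse(p >= 1, pmax(v, cutoff), v))
    pmax(v, 1)
  }
  waist <- gen_exceed("waist", "waist", 80, 90)
  tg <- gen_exceed("tg", "tg", 150, 150)
  glucose <- gen_exceed("glucose", "glucose", 100, 100)
  sbp <- gen_exceed("bp", "sbp", 130, 130)
  dbp <- gen_exceed("bp", "dbp", 85, 85)

  hdl_p <- prm("hdl")
  hdl_sd <- ifelse(is_m, hdl_p$m[2], hdl_p$f[2])
  hdl_cut <- ifelse(is_m, 40, 50)
  hdl_tg <- tgt("hdl")
  hdl <- .mu_below(hdl_cut, hdl_sd, hdl_tg) + hdl_sd * stats::qnorm(u[, "hdl"])
  hdl <- ifelse(hdl_tg <= 0, pmax(hdl, hdl_cut),
                ifelse(hdl_tg >= 1, pmin(hdl, hdl_cut - 1e-6), hdl))
  hdl <- pmax(hdl, 1)

  # BMI rides on the waist latent (r ~ 0.8), published mean/SD, no target
  bmi_p <- prm("bmi")
  z_bmi <- 0.8 * z[, "waist"] + sqrt(1 - 0.8^2) * stats::rnorm(n)
  bmi <- ifelse(is_m, bmi_p$m[1] + bmi_p$m[2] * z_bmi,
                bmi_p$f[1] + bmi_p$f[2] * z_bmi)
  bmi <- pmax(bmi, 12)

  age <- pmin(pmax(stats::rnorm(n, 36.5, 9.5), 20), 70)

  fp <- spec$flag_probs
  cond_flag <- function(positive) {
    stats::runif(n) < ifelse(positive, fp[["treat_given_pos"]],
                             fp[["treat_given_neg"]])
  }
  glu_pos <- glucose >= 100
  bp_pos <- sbp >= 130 | dbp >= 85
  dm_treatment <- cond_flag(glu_pos)
  dm_diagnosis <- dm_treatment | (stats::runif(n) < 0.01)
  sah_treatment <- cond_flag(bp_pos)
  sah_diagnosis <- sah_treatment | (stats::runif(n) < fp[["sah_dx_extra"]])

  coh <- tibble::tibble(
    id = sprintf("S%05d", seq_len(n)),
    sex = sex,
    age_years = age,
    waist_cm = waist, bmi = bmi,
    sbp_mmhg = sbp, dbp_mmhg = dbp,
    glucose_mgdl = glucose, tg_mgdl = tg, hdl_mgdl = hdl,
    dm_diagnosis = dm_diagnosis, dm_treatment = dm_treatment,
    sah_treatment = sah_treatment, sah_diagnosis = sah_diagnosis,
    cvd = stats::runif(n) < fp[["cvd"]],
    pcos = sex == "female" & stats::runif(n) < fp[["pcos"]],
    nafld = stats::runif(n) < fp[["nafld"]],
    acanthosis = stats::runif(n) < fp[["acanthosis"]],
    sedentary = stats::runif(n) < fp[["sedentary"]],
    nonwhite = stats::runif(n) < fp[["nonwhite"]],
    family_history = NA, gestational_dm = NA,
    age_over_40 = age > 40
  )
  attr(coh, "provenance") <- "simulate_cohort"
  coh
}

#' Generate a cohort together with oracle labels
#'
#' The labels are computed by `straight_line_classify()`, a deliberately
#' independent re-implementation of each rule (plain per-record loops and
#' if/else chains, sharing no code with [evaluate_components()]), so the two
#' code paths can be tested against each other.
#'
#' @param spec A [cohort_spec()].
#' @param criterion A [criterion_definition()] from [mets_criteria()] (one of
#'   the six built-ins).
#' @return A list: `cohort` (tibble), `labels` (logical vector).
#' @export
plant_labels <- function(spec, criterion) {
  cohort <- simulate_cohort(spec)
  list(cohort = cohort,
       labels = straight_line_classify(cohort, criterion$name))
}

#' Independent straight-line MetS classification (test oracle)
#'
#' @param cohort A canonical cohort tibble.
#' @param name One of the six built-in criterion names.
#' @return Logical vector of MetS labels.
#' @export
#' @keywords internal
straight_line_classify <- function(cohort, name) {
  n <- nrow(cohort)
  out <- logical(n)
  for (i in seq_len(n)) {
    male <- cohort$sex[i] == "male"
    wc <- cohort$waist_cm[i]; tg <- cohort$tg_mgdl[i]
    hdl <- cohort$hdl_mgdl[i]; glu <- cohort$glucose_mgdl[i]
    sbp <- cohort$sbp_mmhg[i]; dbp <- cohort$dbp_mmhg[i]
    dm <- isTRUE(cohort$dm_diagnosis[i]) || isTRUE(cohort$dm_treatment[i])
    sahtx <- isTRUE(cohort$sah_treatment[i])

    tg_pos <- tg >= 150
    hdl_pos <- if (male) hdl < 40 else hdl < 50
    bp_pos <- sbp >= 130 || dbp >= 85 || sahtx
    glu_pos <- glu >= 100 || dm

    if (name == "IDF_AHA_NHLBI") {
      wc_pos <- if (male) wc >= 90 else wc >= 80
      out[i] <- (wc_pos + tg_pos + hdl_pos + bp_pos + glu_pos) >= 3
    } else if (name == "NCEP_ATPIII") {
      wc_pos <- if (male) wc > 102 else wc > 88
      out[i] <- (wc_pos + tg_pos + hdl_pos + bp_pos + glu_pos) >= 3
    } else if (name == "BARBOSA2006") {
      wc_pos <- if (male) wc > 88 else wc > 84
      out[i] <- (wc_pos + tg_pos + hdl_pos + bp_pos + glu_pos) >= 3
    } else if (name == "IDF") {
      wc_pos <- if (male) wc >= 90 else wc >= 80
      out[i] <- wc_pos && (tg_pos + hdl_pos + bp_pos + glu_pos) >= 2
    } else if (name == "EGIR") {
      gate <- glu >= 110 || dm
      wc_pos <- if (male) wc >= 94 else wc >= 80
      hdl39 <- hdl < 39
      bp_pos2 <- sbp >= 140 || dbp >= 90 || sahtx
      out[i] <- gate && (wc_pos + tg_pos + hdl39 + bp_pos2) >= 2
    } else if (name == "AACE") {
      risk <- isTRUE(cohort$cvd[i]) || isTRUE(cohort$sah_diagnosis[i]) ||
        isTRUE(cohort$pcos[i]) || isTRUE(cohort$nafld[i]) ||
        isTRUE(cohort$acanthosis[i]) || isTRUE(cohort$family_history[i]) ||
        isTRUE(cohort$gestational_dm[i]) || isTRUE(cohort$nonwhite[i]) ||
        isTRUE(cohort$sedentary[i]) || cohort$age_years[i] > 40 ||
        (!is.na(cohort$bmi[i]) && cohort$bmi[i] >= 25) ||
        (if (male) wc > 94 else wc > 80)
      bp_aace <- sbp >= 130 || dbp >= 85 || sahtx
      out[i] <- risk && (tg_pos + hdl_pos + bp_aace) >= 2
    } else {
      stop("unknown criterion name: ", name, call. = FALSE)
    }
  }
  out
}
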