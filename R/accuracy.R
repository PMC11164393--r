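#' Build a 2x2 confusion table against a gold standard
#'
#' Counts are named as in the diagnostic-accuracy literature: `a`
#' true-positive, `b` false-positive, `c` false-negative, `d` true-negative.
#'
#' @param gold,test Logical vectors of equal length (no NAs): the gold
#'   standard classification and the index-test classification.
#' @return An object of class `confusion_table` (list `a`, `b`, `c`, `d`).
#' @export
#' @examples
#' build_confusion(gold = c(TRUE, TRUE, FALSE), test = c(TRUE, FALSE, FALSE))
build_confusion <- function(gold, test) {
  if (length(gold) != length(test)) {
    stop("gold and test vectors differ in length", call. = FALSE)
  }
  if (length(gold) == 0L) stop("empty label vectors", call. = FALSE)
  if (anyNA(gold) || anyNA(test)) stop("labels contain NA", call. = FALSE)
  confusion_table(
    a = sum(gold & test), b = sum(!gold & test),
    c = sum(gold & !test), d = sum(!gold & !test)
  )
}

#' Construct a confusion table from its four cells
#' @param a,b,c,d Non-negative integer counts: true-positive, false-positive,
#'   false-negative, true-negative.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table (n = 0)", call. = FALSE)
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("test +", "test -"), c("gold +", "gold -")))
  cat("<confusion_table> n =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles; the lower bound is 0 when
#' `successes = 0` and the upper bound is 1 when `successes = trials`.
#'
#' @param successes,trials Non-negative integer counts, `successes <= trials`,
#'   `trials > 0`.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
#' @examples
#' exact_ci(52, 52)   # lower bound 0.932: a 100% estimate from 52 trials
exact_ci <- function(successes, trials, level = 0.95) {
  if (trials <= 0 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    stop("invalid counts: need 0 <= successes <= trials, trials > 0",
         call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = max(0, lower), upper = min(1, upper))
}

metric_row <- function(metric, num, den, level) {
  if (den == 0) {
    return(tibble::tibble(metric = metric, estimate = NA_real_,
                          conf_low = NA_real_, conf_high = NA_real_,
                          numerator = num, denominator = den))
  }
  ci <- exact_ci(num, den, level = level)
  tibble::tibble(metric = metric, estimate = num / den,
                 conf_low = ci[[1]], conf_high = ci[[2]],
                 numerator = num, denominator = den)
}

#' Sensitivity, specificity and predictive values with exact CIs
#'
#' Point estimates follow the standard 2x2 formulas -- Se = a/(a+c),
#' Sp = d/(b+d), PPV = a/(a+b), NPV = d/(c+d) -- with Clopper-Pearson exact
#' 95% intervals. Predictive values are therefore at the cohort's
#' gold-standard prevalence. A metric whose denominator is zero is returned
#' as `NA`, not an error.
#'
#' @param x A `confusion_table`.
#' @param level Confidence level.
#' @return A tibble with one row per metric (`se`, `sp`, `ppv`, `npv`):
#'   `estimate`, `conf_low`, `conf_high` (proportions), plus the counts.
#' @export
#' @examples
#' accuracy_metrics(confusion_table(330, 0, 17, 764))
accuracy_metrics <- function(x, level = 0.95) {
  stopifnot(inherits(x, "confusion_table"))
  dplyr::bind_rows(
    metric_row("se", x$a, x$a + x$c, level),
    metric_row("sp", x$d, x$b + x$d, level),
    metric_row("ppv", x$a, x$a + x$b, level),
    metric_row("npv", x$d, x$c + x$d, level)
  )
}

#' Positive and negative likelihood ratios with log-method CIs
#'
#' LR+ = Se/(1-Sp) and LR- = (1-Se)/Sp. When the table has no false
#' positives (b = 0, Sp = 1) the positive likelihood ratio is undefined and
#' returned as `NA` -- the tabular rendering of "estimate not obtained due to
#' the absence of false positives"; symmetrically LR- is undefined when
#' d = 0. Confidence intervals use the Simel log method:
#' `ln LR+ +/- z * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d))`, and analogously with
#' `c`, `d` for LR-.
#'
#' @param x A `confusion_table`.
#' @param level Confidence level.
#' @return A tibble with rows `lr_pos`, `lr_neg`: `estimate`, `conf_low`,
#'   `conf_high` (NA where undefined).
#' @export
#' @examples
#' likelihood_ratios(confusion_table(144, 4, 203, 760))
likelihood_ratios <- function(x, level = 0.95) {
  stopifnot(inherits(x, "confusion_table"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  na_row <- function(which) tibble::tibble(
    metric = which, estimate = NA_real_,
    conf_low = NA_real_, conf_high = NA_real_)
  if (x$a + x$c == 0 || x$b + x$d == 0) {
    return(dplyr::bind_rows(na_row("lr_pos"), na_row("lr_neg")))
  }
  se <- x$a / (x$a + x$c)
  sp <- x$d / (x$b + x$d)
  pos <- if (x$b == 0) na_row("lr_pos") else {
    est <- se / (1 - sp)
    if (x$a == 0) {
      tibble::tibble(metric = "lr_pos", estimate = est,
                     conf_low = NA_real_, conf_high = NA_real_)
    } else {
      s <- sqrt(1 / x$a - 1 / (x$a + x$c) + 1 / x$b - 1 / (x$b + x$d))
      tibble::tibble(metric = "lr_pos", estimate = est,
                     conf_low = exp(log(est) - z * s),
                     conf_high = exp(log(est) + z * s))
    }
  }
  neg <- if (x$d == 0) na_row("lr_neg") else {
    est <- (1 - se) / sp
    if (x$c == 0) {
      tibble::tibble(metric = "lr_neg", estimate = est,
                     conf_low = NA_real_, conf_high = NA_real_)
    } else {
      s <- sqrt(1 / x$c - 1 / (x$a + x$c) + 1 / x$d - 1 / (x$b + x$d))
      tibble::tibble(metric = "lr_neg", estimate = est,
                     conf_low = exp(log(est) - z * s),
                     conf_high = exp(log(est) + z * s))
    }
  }
  dplyr::bind_rows(pos, neg)
}

#' Agreement band for a kappa value
#'
#' Half-open bands with inclusive upper bounds: kappa <= 0.20 slight,
#' (0.20, 0.40] fair, (0.40, 0.60] moderate, (0.60, 0.80] substantial,
#' > 0.80 almost perfect.
#'
#' @param kappa Numeric kappa value(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
kappa_band <- function(kappa) {
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)` with observed
#' agreement `Po = (a+d)/n` and chance agreement
#' `Pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. Degenerate marginals (`Pe = 1`)
#' make kappa undefined and return `NA`.
#'
#' @param x A `confusion_table`.
#' @return A one-row tibble: `kappa`, `po`, `pe`, `band`.
#' @export
#' @examples
#' cohen_kappa(confusion_table(330, 0, 17, 764))
cohen_kappa <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  n <- x$a + x$b + x$c + x$d
  po <- (x$a + x$d) / n
  pe <- ((x$a + x$b) * (x$a + x$c) + (x$c + x$d) * (x$b + x$d)) / n^2
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  tibble::tibble(kappa = kappa, po = po, pe = pe, band = kappa_band(kappa))
}

#' Reconstruct a 2x2 table from published summary counts
#'
#' Diagnostic-accuracy reports often print only the cohort size, the number
#' of gold-standard positives, each index test's number of positives and its
#' positive predictive value. Those four numbers determine the full 2x2
#' table: `a = round(ppv * test_pos)`, `b = test_pos - a`, `c = gold_pos - a`,
#' `d = n - gold_pos - b`.
#'
#' @param n Total cohort size.
#' @param gold_pos Gold-standard positive count.
#' @param test_pos Index-test positive count.
#' @param ppv Positive predictive value as a proportion (ignored when
#'   `test_pos = 0`).
#' @return A `confusion_table`.
#' @export
#' @examples
#' reconstruct_confusion(1111, 347, 330, 1.00)   # (330, 0, 17, 764)
reconstruct_confusion <- function(n, gold_pos, test_pos, ppv = 1) {
  if (gold_pos < 0 || gold_pos > n || test_pos < 0 || test_pos > n) {
    stop("counts out of range", call. = FALSE)
  }
  if (test_pos == 0) {
    return(confusion_table(0, 0, gold_pos, n - gold_pos))
  }
  if (is.na(ppv) || ppv < 0 || ppv > 1) stop("ppv must be in [0, 1]",
                                             call. = FALSE)
  a <- round(ppv * test_pos)
  b <- test_pos - a
  c <- gold_pos - a
  d <- n - gold_pos - b
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) {
    bad <- names(cells)[cells < 0]
    stop("inconsistent summary counts: cell(s) ",
         paste(bad, collapse = ", "), " negative", call. = FALSE)
  }
  confusion_table(a, b, c, d)
}

#' Full accuracy report for one index test against the gold standard
#'
#' @param x A `confusion_table`, or a logical gold vector (with `test`).
#' @param test Logical index-test vector when `x` is the gold vector.
#' @param level Confidence level.
#' @return An object of class `mets_accuracy`: a tibble with one row per
#'   metric (`se`, `sp`, `ppv`, `npv`, `lr_pos`, `lr_neg`, `kappa`),
#'   estimates and confidence bounds (proportion/ratio scale; kappa has no
#'   CI), and a `band` column filled for the kappa row.
#' @export
#' @examples
#' accuracy_report(confusion_table(144, 4, 203, 760))
accuracy_report <- function(x, test = NULL, level = 0.95) {
  if (!inherits(x, "confusion_table")) x <- build_confusion(x, test)
  kap <- cohen_kappa(x)
  out <- dplyr::bind_rows(
    accuracy_metrics(x, level = level),
    likelihood_ratios(x, level = level),
    tibble::tibble(metric = "kappa", estimate = kap$kappa,
                   conf_low = NA_real_, conf_high = NA_real_)
  )
  out$band <- ifelse(out$metric == "kappa", kap$band, NA_character_)
  class(out) <- c("mets_accuracy", class(out))
  attr(out, "confusion") <- x
  out
}

#' Accuracy of several MetS definitions against a gold-standard column
#'
#' @param labels A label matrix from [classify_cohort()]: tibble with `id`
#'   and one logical column per criterion.
#' @param gold Name of the gold-standard column (default `"IDF_AHA_NHLBI"`).
#' @param level Confidence level.
#' @return A tibble: one row per (criterion, metric) with estimates, CIs, the
#'   kappa band, and the underlying 2x2 cells `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n = 200, seed = 3))
#' compare_criteria(classify_cohort(coh))
compare_criteria <- function(labels, gold = "IDF_AHA_NHLBI", level = 0.95) {
  if (!gold %in% names(labels)) {
    stop("gold-standard column not found: ", gold, call. = FALSE)
  }
  tests <- setdiff(names(labels), c("id", "sex", gold))
  purrr::map_dfr(tests, function(nm) {
    ct <- build_confusion(labels[[gold]], labels[[nm]])
    rep <- accuracy_report(ct, level = level)
    tibble::tibble(criterion = nm, metric = rep$metric,
                   estimate = rep$estimate, conf_low = rep$conf_low,
                   conf_high = rep$conf_high, band = rep$band,
                   a = ct$a, b = ct$b, c = ct$c, d = ct$d)
  })
}

#' Format an accuracy report the way diagnostic tables print it
#'
#' Percentages to 1 decimal place, kappa to 4 decimals, likelihood ratios to
#' 3 significant figures; undefined estimates rendered as `"-"`.
#'
#' @param report A `mets_accuracy` tibble from [accuracy_report()].
#' @return A tibble `metric`, `display` (character).
#' @export
format_accuracy <- function(report) {
  fmt1 <- function(p) formatC(round(100 * p, 1), format = "f", digits = 1)
  fmt3 <- function(x) signif(x, 3)
  disp <- purrr::pmap_chr(
    list(report$metric, report$estimate, report$conf_low, report$conf_high),
    function(m, est, lo, hi) {
      if (is.na(est)) return("-")
      if (m %in% c("se", "sp", "ppv", "npv")) {
        sprintf("%s (%s-%s)", fmt1(est), fmt1(lo), fmt1(hi))
      } else if (m == "kappa") {
        sprintf("%.4f", est)
      } else if (is.na(lo)) {
        as.character(fmt3(est))
      } else {
        sprintf("%s (%s-%s)", fmt3(est), fmt3(lo), fmt3(hi))
      }
    })
  tibble::tibble(metric = report$metric, display = disp)
}

#' @rdname tidy.confusion_table
#' @export
glance.confusion_table <- function(x, ...) {
  n <- x$a + x$b + x$c + x$d
  kap <- cohen_kappa(x)
  tibble::tibble(n = n, a = x$a, b = x$b, c = x$c, d = x$d,
                 prevalence = (x$a + x$c) / n,
                 accuracy = (x$a + x$d) / n,
                 kappa = kap$kappa, band = kap$band)
}

#' Broom-style tidiers for confusion tables
#'
#' `tidy()` returns the full metric table of [accuracy_report()]; `glance()`
#' returns a one-row summary (n, cells, prevalence, raw accuracy, kappa).
#'
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.confusion_table <- function(x, ...) {
  out <- accuracy_report(x)
  class(out) <- class(tibble::tibble())
  out
}
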