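## Predictor screening for suction-related HR changes (Table-3-style).

#' Build the SE-level analysis table for predictor screening
#'
#' Joins each classified suction event with its newborn's covariates and
#' defines the binary outcome `y`: 1 when the SE response is a
#' suction-related change (fall or arrhythmia), 0 otherwise
#' (ventilation-cessation falls and no-change SEs). `INDETERMINATE` SEs are
#' dropped.
#'
#' @param classified Result of [classify_cohort()].
#' @return `data.frame` with one row per analysable SE: `newborn_id`, `y`,
#'   `female`, `amniotic_fluid`, `catheter`, `ventilation_prior`,
#'   `stimulation_prior`, `ga_weeks`, `birthweight_g`, `first_hr_bpm`,
#'   `time_to_se_s`, `pre_hr_bpm`, `se_duration_s`.
#' @export
build_screen_data <- function(classified) {
  r <- classified$responses
  if (!nrow(r)) stop("no classified suction events")
  r <- r[r$label != "INDETERMINATE", , drop = FALSE]
  data.frame(
    newborn_id = r$newborn_id,
    y = as.integer(r$label %in% c("SUCTION_RELATED_FALL",
                                  "SUCTION_RELATED_ARRHYTHMIA")),
    female = as.integer(r$sex == "female"),
    amniotic_fluid = r$amniotic_fluid,
    catheter = as.integer(r$device == "catheter"),
    ventilation_prior = as.integer(r$ventilation_prior),
    stimulation_prior = as.integer(r$stimulation_prior),
    ga_weeks = r$ga_weeks,
    birthweight_g = r$birthweight_g,
    first_hr_bpm = r$first_hr_bpm,
    time_to_se_s = r$start_s,
    pre_hr_bpm = r$pre_hr_bpm,
    se_duration_s = r$duration_s,
    stringsAsFactors = FALSE
  )
}

screen_one_categorical <- function(dat, var, label) {
  x <- dat[[var]]
  keep <- !is.na(x) & !is.na(dat$y)
  x <- x[keep]
  if (length(unique(x)) < 2L) {
    warning(sprintf("predictor '%s' has a single level; skipped", var))
    return(NULL)
  }
  X <- cbind(`(Intercept)` = 1, stats::model.matrix(~x)[, -1, drop = FALSE])
  fit <- tryCatch(fit_logit_cluster(dat$y[keep], X, dat$newborn_id[keep]),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning(sprintf("predictor '%s': model not estimable; skipped", var))
    return(NULL)
  }
  terms <- setdiff(names(fit$coefficients), "(Intercept)")
  out <- lapply(terms, function(tm) {
    orr <- odds_ratio(fit, tm)
    w <- wald_test(fit, tm)
    data.frame(predictor = label, level = sub("^x", "", tm), type = "categorical",
               or = orr$or, ci_lo = orr$ci_lo, ci_hi = orr$ci_hi,
               p = w$p, p_nl = NA_real_, or_scale = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

screen_one_continuous <- function(dat, var, label, scale) {
  x <- dat[[var]]
  keep <- !is.na(x) & !is.na(dat$y)
  x <- x[keep]; y <- dat$y[keep]; cl <- dat$newborn_id[keep]
  if (length(unique(x)) < 10L) {
    warning(sprintf("predictor '%s': too few distinct values for a spline; skipped",
                    var))
    return(NULL)
  }
  fit <- tryCatch(fit_rcs_logit(y, x, cl), error = function(e) NULL)
  if (is.null(fit)) {
    warning(sprintf("predictor '%s': spline model not estimable; skipped", var))
    return(NULL)
  }
  p_nl <- wald_test(fit, "x_nl")$p
  p_all <- wald_test(fit, c("x", "x_nl"))$p
  if (p_nl > 0.05) {
    # linearity assumed: refit the plain linear model and report the OR
    Xl <- cbind(`(Intercept)` = 1, x = x)
    lin <- tryCatch(fit_logit_cluster(y, Xl, cl), error = function(e) NULL)
    if (!is.null(lin)) {
      orr <- odds_ratio(lin, "x", unit_scale = scale)
      w <- wald_test(lin, "x")
      return(data.frame(predictor = label, level = "", type = "continuous",
                        or = orr$or, ci_lo = orr$ci_lo, ci_hi = orr$ci_hi,
                        p = w$p, p_nl = p_nl, or_scale = scale,
                        stringsAsFactors = FALSE))
    }
  }
  # significant nonlinearity: no single OR; report the overall spline test
  data.frame(predictor = label, level = "", type = "continuous_nonlinear",
             or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
             p = p_all, p_nl = p_nl, or_scale = scale, stringsAsFactors = FALSE)
}

#' Screen potential predictors of suction-related HR changes
#'
#' For each categorical predictor, a cluster-robust logistic odds ratio
#' against the reference level; for each continuous predictor, a three-knot
#' restricted-cubic-spline logistic model with Wald tests of the overall
#' and nonlinear effects. When the nonlinearity p-value exceeds 0.05 the
#' effect is assumed linear and the OR is reported per the conventional
#' unit (per 100 g birthweight, per 10 bpm first observed HR, per 10 s time
#' to SE); otherwise the overall chi-square p is reported and the effect
#' should be displayed with [probability_curve()]. Degenerate predictors
#' (a single level) are skipped with a warning.
#'
#' @param screen_data From [build_screen_data()].
#' @return `data.frame` with columns `predictor`, `level`, `type`, `or`,
#'   `ci_lo`, `ci_hi`, `p`, `p_nl`, `or_scale`.
#' @export
predictor_screen <- function(screen_data) {
  dat <- screen_data
  rows <- list(
    screen_one_categorical(dat, "female", "Female"),
    screen_one_categorical(dat, "amniotic_fluid", "Amniotic fluid"),
    screen_one_categorical(dat, "catheter", "Catheter (vs bulb)"),
    screen_one_categorical(dat, "ventilation_prior", "Ventilation prior to SE"),
    screen_one_categorical(dat, "stimulation_prior", "Stimulation prior to SE"),
    screen_one_continuous(dat, "ga_weeks", "Gestational age (weeks)", 1),
    screen_one_continuous(dat, "birthweight_g", "Birthweight (g)", 100),
    screen_one_continuous(dat, "first_hr_bpm", "First observed HR (bpm)", 10),
    screen_one_continuous(dat, "time_to_se_s", "Time post delivery to SE (s)", 10),
    screen_one_continuous(dat, "pre_hr_bpm", "HR prior to SE (bpm)", 1),
    screen_one_continuous(dat, "se_duration_s", "Duration of SE (s)", 1)
  )
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
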