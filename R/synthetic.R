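## Synthetic resuscitation cohort generator with known ground truth.
##
## Every downstream stage (segmentation, HR-response classification,
## statistics) is testable against the planted truth because the study's raw
## data cannot be shared. Default rates and distributions are calibrated to
## the published cohort descriptives; see the package vignette.

#' Scenario configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published cohort's headline rates: 91% of newborns
#' suctioned; a median of 2 SEs per suctioned baby (quartiles 1-4); SE
#' duration median 14 s (quartiles ~7-23, lognormal); mean 3.6 insertions
#' per SE; 22% of babies receiving at least one catheter suction; 12.6% of
#' SEs with a suction-related HR change and 8.1% with a
#' ventilation-cessation fall; death probability 0.64 given at least one
#' suction-related change and 0.28 otherwise.
#'
#' The per-SE probability of a suction-related change depends on the
#' baseline heart rate at the SE through an inverted-U weight peaked at
#' `hr_effect_peak_bpm` (changes are most likely for pre-SE HR in the normal
#' range, ~100-170 bpm); the weight is normalized by the fixed constant
#' `hr_effect_norm` so that the cohort-average per-SE change probability
#' equals `p_suction_related_change`.
#'
#' @param n_newborns Number of newborns in the cohort.
#' @param seed Integer master seed; fixed seed gives bit-identical cohorts.
#' @param p_suctioned Probability a newborn receives at least one SE.
#' @param n_se_probs Probabilities over 1..8 SEs for suctioned newborns.
#' @param se_duration_meanlog,se_duration_sdlog Lognormal parameters of SE
#'   duration in seconds.
#' @param insertion_rate Mean of the (1 + Poisson) insertions-per-SE count.
#' @param p_catheter Probability a newborn is a catheter user (at least one
#'   catheter SE; others use the bulb device).
#' @param p_suction_related_change Marginal per-SE probability of a planted
#'   suction-related HR change (fall or arrhythmia).
#' @param p_arrhythmia_share Fraction of suction-related changes planted as
#'   bigeminy rather than a fall (study: 1 of 17).
#' @param p_vent_cessation_change Per-SE probability of a planted
#'   ventilation-cessation fall (requires a ventilated newborn).
#' @param planted_fall_fraction Relative depth of planted suction-related
#'   falls (fraction of the pre-SE heart rate).
#' @param planted_vent_fall_bpm Absolute depth, in bpm, of planted
#'   ventilation-cessation falls.
#' @param p_death_given_change,p_death_given_no_change Death (<= 3 days)
#'   probabilities given at least one / no suction-related change truth.
#' @param hr_noise_sd_bpm SD of additive Gaussian HR noise, bpm.
#' @param p_missing_hr Probability each HR sample is missing (dropout).
#' @param episode_duration_meanlog,episode_duration_sdlog,episode_duration_min,episode_duration_max
#'   Lognormal parameters and clamp range of episode duration, seconds.
#' @param hr_effect Logical; plant the inverted-U HR dependence?
#' @param hr_effect_peak_bpm,hr_effect_sd_bpm Peak and width (bpm) of the
#'   Gaussian inverted-U weight.
#' @param hr_effect_norm Fixed normalization constant (design-time Monte
#'   Carlo estimate of the mean weight under the baseline model).
#' @param vent_cessation_norm Fixed normalization constant compensating for
#'   SEs ineligible for a ventilation-cessation fall (unventilated newborns
#'   and baselines too low to fall >30 bpm from), so that the marginal
#'   per-SE rate equals `p_vent_cessation_change`; design-time Monte Carlo
#'   estimate.
#' @param p_ventilated Probability a newborn receives ventilation bouts.
#' @param p_vent_prior,p_stim_prior Probabilities that a ventilation /
#'   stimulation bout is placed shortly before (but not concurrent with) an
#'   SE, exercising the prior-intervention flags.
#' @param p_beats Probability a newborn without planted arrhythmia still has
#'   beat-time data (newborns with planted arrhythmia always do).
#' @return Object of class `ns_scenario` (validated named list).
#' @export
scenario_config <- function(n_newborns,
                            seed = 1L,
                            p_suctioned = 0.91,
                            n_se_probs = c(0.30, 0.25, 0.15, 0.12, 0.08, 0.05, 0.03, 0.02),
                            se_duration_meanlog = log(14),
                            se_duration_sdlog = 0.88,
                            insertion_rate = 2.6,
                            p_catheter = 0.22,
                            p_suction_related_change = 0.126,
                            p_arrhythmia_share = 1 / 17,
                            p_vent_cessation_change = 0.081,
                            planted_fall_fraction = 0.25,
                            planted_vent_fall_bpm = 40,
                            p_death_given_change = 0.64,
                            p_death_given_no_change = 0.28,
                            hr_noise_sd_bpm = 3,
                            p_missing_hr = 0.05,
                            episode_duration_meanlog = log(390),
                            episode_duration_sdlog = 0.74,
                            episode_duration_min = 100,
                            episode_duration_max = 1500,
                            hr_effect = TRUE,
                            hr_effect_peak_bpm = 135,
                            hr_effect_sd_bpm = 40,
                            hr_effect_norm = 0.667,
                            vent_cessation_norm = 0.666,
                            p_ventilated = 0.85,
                            p_vent_prior = 0.5,
                            p_stim_prior = 0.65,
                            p_beats = 0.3) {
  sc <- as.list(environment())
  if (!is.numeric(n_newborns) || n_newborns < 1)
    stop("n_newborns must be >= 1")
  props <- c("p_suctioned", "p_catheter", "p_suction_related_change",
             "p_arrhythmia_share", "p_vent_cessation_change",
             "planted_fall_fraction", "p_death_given_change",
             "p_death_given_no_change", "p_missing_hr", "p_ventilated",
             "p_vent_prior", "p_stim_prior", "p_beats")
  for (nm in props)
    if (sc[[nm]] < 0 || sc[[nm]] > 1)
      stop(sprintf("%s must lie in [0, 1]", nm))
  if (abs(sum(sc$n_se_probs) - 1) > 1e-8 || any(sc$n_se_probs < 0))
    stop("n_se_probs must be a probability vector over 1..8 SEs")
  if (sc$episode_duration_min <= 0 ||
      sc$episode_duration_max < sc$episode_duration_min)
    stop("invalid episode duration range")
  if (sc$episode_duration_max < 45)
    stop("degenerate scenario: episodes too short to hold one suction event")
  structure(sc, class = "ns_scenario")
}

## inverted-U weight on baseline HR (bpm) at the SE
hr_change_weight <- function(h, sc) {
  if (!sc$hr_effect) return(rep(1, length(h)))
  exp(-((h - sc$hr_effect_peak_bpm) / sc$hr_effect_sd_bpm)^2 / 2) / sc$hr_effect_norm
}

## piecewise-linear dip shape: 0 -> 1 over 2 s, hold 10 s, 1 -> 0 over 13 s
dip_shape <- function(t, t0) {
  u <- t - t0
  s <- numeric(length(t))
  s[u >= 0 & u < 2] <- u[u >= 0 & u < 2] / 2
  s[u >= 2 & u < 12] <- 1
  ramp <- u >= 12 & u < 25
  s[ramp] <- (25 - u[ramp]) / 13
  s
}

#' Generate one synthetic resuscitation episode
#'
#' Builds an episode whose heart-rate stream is a piecewise-linear recovery
#' trajectory (from the first observed HR toward a 120-170 bpm plateau) plus
#' Gaussian noise and random dropout, with planted responses:
#' suction-related falls dip by `planted_fall_fraction` of the pre-SE level
#' inside the SE and recover within 40 s with no ventilation overlapping the
#' dip; ventilation-cessation falls follow a ventilation bout ending at most
#' 5 s before the SE and dip by at least `planted_vent_fall_bpm`; arrhythmia
#' truths plant a bigeminy segment (alternating short/long RR intervals) in
#' the beat-time series overlapping the SE.
#'
#' @param scenario An [scenario_config()].
#' @param episode_seed Integer seed for this episode's RNG stream.
#' @param id Newborn identifier.
#' @return A list with `episode` (an `ns_episode`) and `truth` (a
#'   `data.frame` with one row per planted SE: `newborn_id`, `se_index`,
#'   `truth_label`, `se_start_s`, `se_stop_s`, `baseline_pre_bpm`,
#'   `planted_fall_fraction`, `planted_fall_bpm`, `arr_start_s`,
#'   `arr_stop_s`).
#' @export
generate_episode <- function(scenario, episode_seed, id = "nb1") {
  sc <- scenario
  if (!inherits(sc, "ns_scenario")) stop("scenario must be an ns_scenario")
  set.seed(as.integer(episode_seed) %% .Machine$integer.max)

  ## covariates
  first_hr <- min(max(stats::rlnorm(1, log(77), 0.69), 30), 220)
  bw <- min(max(stats::rnorm(1, 3060, 560), 1000), 6000)
  ga <- min(max(stats::rnorm(1, 38.1, 1.6), 34), 43)
  sex <- if (stats::runif(1) < 0.34) "female" else "male"
  amniotic <- sample(AMNIOTIC, 1, prob = c(0.52, 0.15, 0.33))
  ventilated <- stats::runif(1) < sc$p_ventilated

  duration <- min(max(stats::rlnorm(1, sc$episode_duration_meanlog,
                                    sc$episode_duration_sdlog),
                      sc$episode_duration_min), sc$episode_duration_max)
  duration <- round(duration)

  plateau <- stats::runif(1, 120, 170)
  t_rec <- stats::runif(1, 120, 300)
  ## cap the decline rate of high-first-HR trajectories at 0.15 bpm/s so the
  ## baseline itself can never produce a >15% fall within an SE assessment
  ## window (up to 110 s for the longest SEs)
  if (first_hr > plateau) t_rec <- max(t_rec, (first_hr - plateau) / 0.15)
  baseline <- function(t) first_hr + (plateau - first_hr) * pmin(1, t / t_rec)

  ## ---- suction events ----
  window_end <- min(duration, 440)
  se_list <- list()
  truth <- list()
  suctioned <- stats::runif(1) < sc$p_suctioned
  catheter_user <- stats::runif(1) < sc$p_catheter
  n_se_target <- if (suctioned)
    sample(seq_along(sc$n_se_probs), 1, prob = sc$n_se_probs) else 0L

  if (suctioned && window_end < 45)
    stop("degenerate scenario: episode too short to hold one suction event")

  events <- list()
  cursor <- 30
  for (k in seq_len(n_se_target)) {
    se_dur <- min(max(stats::rlnorm(1, sc$se_duration_meanlog,
                                    sc$se_duration_sdlog), 3), 90)
    start <- cursor + stats::runif(1, 0, 20)
    if (start + min(se_dur, 3) > window_end - 5 || start + 26 > duration) break
    se_dur <- min(se_dur, window_end - 5 - start)

    n_ins <- 1L + stats::rpois(1, sc$insertion_rate)
    gaps <- if (n_ins > 1L) stats::runif(n_ins - 1L, 0.5, 4.5) else numeric()
    ins_total <- max(se_dur - sum(gaps), 0.6 * n_ins)
    wts <- stats::runif(n_ins, 0.5, 1.5)
    ins_dur <- pmax(ins_total * wts / sum(wts), 0.3)
    starts <- numeric(n_ins)
    t_i <- start
    for (j in seq_len(n_ins)) {
      starts[j] <- t_i
      t_i <- t_i + ins_dur[j] + if (j < n_ins) gaps[j] else 0
    }
    stop_se <- starts[n_ins] + ins_dur[n_ins]
    device <- if (catheter_user && (k == 1L || stats::runif(1) < 0.6))
      "catheter" else "bulb"
    sites <- ifelse(stats::runif(n_ins) < 0.6, "mouth", "nose")

    events[[length(events) + 1L]] <- data.frame(
      kind = "suction_insertion",
      start_s = round(starts, 3), stop_s = round(starts + ins_dur, 3),
      site = sites, device = device, obscured = FALSE,
      stringsAsFactors = FALSE)

    h_at_se <- baseline(start)
    u <- stats::runif(1)
    p_chg <- min(sc$p_suction_related_change * hr_change_weight(h_at_se, sc), 0.95)
    p_vc <- if (ventilated)
      min(sc$p_vent_cessation_change / sc$vent_cessation_norm, 0.5) else 0
    lbl <- if (u < p_chg) {
      if (stats::runif(1) < sc$p_arrhythmia_share) "SUCTION_RELATED_ARRHYTHMIA"
      else "SUCTION_RELATED_FALL"
    } else if (u < p_chg + p_vc &&
               h_at_se >= sc$planted_vent_fall_bpm + 45) {
      ## a >30 bpm fall needs enough heart rate to fall from; low-baseline
      ## SEs cannot host a ventilation-cessation fall
      "VENT_CESSATION_FALL"
    } else "NO_CHANGE"

    se_list[[k]] <- list(start = start, stop = stop_se, label = lbl,
                         h_pre = h_at_se)
    truth[[k]] <- data.frame(
      newborn_id = id, se_index = k, truth_label = lbl,
      se_start_s = start, se_stop_s = stop_se, baseline_pre_bpm = h_at_se,
      planted_fall_fraction =
        if (lbl == "SUCTION_RELATED_FALL") sc$planted_fall_fraction else NA_real_,
      planted_fall_bpm =
        if (lbl == "VENT_CESSATION_FALL") sc$planted_vent_fall_bpm else NA_real_,
      arr_start_s = NA_real_, arr_stop_s = NA_real_,
      stringsAsFactors = FALSE)

    cursor <- stop_se + 45
  }
  n_se <- length(se_list)

  ## ---- ventilation / stimulation / covering bouts ----
  if (ventilated) {
    for (k in seq_len(n_se)) {
      se <- se_list[[k]]
      if (se$label == "VENT_CESSATION_FALL") {
        g <- stats::runif(1, 1, 4)
        len <- stats::runif(1, 10, 30)
        events[[length(events) + 1L]] <- data.frame(
          kind = "ventilation", start_s = round(max(se$start - g - len, 0), 3),
          stop_s = round(se$start - g, 3), site = NA_character_,
          device = NA_character_, obscured = FALSE, stringsAsFactors = FALSE)
      } else if (stats::runif(1) < sc$p_vent_prior) {
        g <- stats::runif(1, 8, 18)
        len <- stats::runif(1, 5, 20)
        events[[length(events) + 1L]] <- data.frame(
          kind = "ventilation", start_s = round(max(se$start - g - len, 0), 3),
          stop_s = round(se$start - g, 3), site = NA_character_,
          device = NA_character_, obscured = FALSE, stringsAsFactors = FALSE)
      }
    }
    ## background bouts clear of every SE assessment window
    bounds <- if (n_se) vapply(se_list, function(s) c(s$start, s$stop),
                               numeric(2)) else NULL
    slot_start <- if (n_se) max(bounds[2, ]) + 45 else 30
    while (slot_start + 10 < duration - 5 && stats::runif(1) < 0.6) {
      len <- stats::runif(1, 10, 40)
      stop_b <- min(slot_start + len, duration - 1)
      events[[length(events) + 1L]] <- data.frame(
        kind = "ventilation", start_s = round(slot_start, 3),
        stop_s = round(stop_b, 3), site = NA_character_,
        device = NA_character_, obscured = FALSE, stringsAsFactors = FALSE)
      slot_start <- stop_b + stats::runif(1, 15, 60)
    }
  }
  for (k in seq_len(n_se)) {
    se <- se_list[[k]]
    if (stats::runif(1) < sc$p_stim_prior) {
      g <- stats::runif(1, 2, 15)
      len <- stats::runif(1, 3, 10)
      events[[length(events) + 1L]] <- data.frame(
        kind = "stimulation", start_s = round(max(se$start - g - len, 0), 3),
        stop_s = round(se$start - g, 3), site = NA_character_,
        device = NA_character_, obscured = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (stats::runif(1) < 0.5 && duration > 40)
    events[[length(events) + 1L]] <- data.frame(
      kind = "covering", start_s = round(stats::runif(1, 0, 10), 3),
      stop_s = round(stats::runif(1, 20, 35), 3), site = NA_character_,
      device = NA_character_, obscured = FALSE, stringsAsFactors = FALSE)

  ev <- if (length(events)) do.call(rbind, events) else
    interval_events()
  ev <- ev[order(ev$start_s, ev$stop_s), , drop = FALSE]
  rownames(ev) <- NULL

  ## ---- heart-rate stream: baseline + planted dips + noise ----
  t_s <- seq(1, duration, by = 1)
  h <- baseline(t_s)
  for (k in seq_len(n_se)) {
    se <- se_list[[k]]
    if (se$label == "SUCTION_RELATED_FALL") {
      depth <- sc$planted_fall_fraction * se$h_pre
      h <- h - depth * dip_shape(t_s, se$start + 1)
    } else if (se$label == "VENT_CESSATION_FALL") {
      depth <- sc$planted_vent_fall_bpm + stats::runif(1, 2, 10)
      h <- h - depth * dip_shape(t_s, se$start + 1)
    }
  }
  hr_noisefree <- h
  h <- h + stats::rnorm(length(h), 0, sc$hr_noise_sd_bpm)
  h <- pmin(pmax(h, 25), 250)
  keep <- stats::runif(length(h)) >= sc$p_missing_hr
  hr <- data.frame(t_s = t_s[keep], hr_bpm = round(h[keep], 1))

  ## ---- beat-time series ----
  any_arr <- n_se > 0 &&
    any(vapply(se_list, function(s) s$label == "SUCTION_RELATED_ARRHYTHMIA",
               logical(1)))
  beats <- NULL
  if (any_arr || stats::runif(1) < sc$p_beats) {
    bt <- numeric(0)
    t_b <- 0.5
    while (t_b < duration) {
      bt[length(bt) + 1L] <- t_b
      rr <- 60 / baseline(t_b) * exp(stats::rnorm(1, 0, 0.02))
      t_b <- t_b + min(max(rr, 0.25), 2.5)
    }
    for (k in seq_len(n_se)) {
      se <- se_list[[k]]
      if (se$label != "SUCTION_RELATED_ARRHYTHMIA") next
      arr_len <- max(10, min(se$stop - se$start, 20))
      arr_iv <- c(se$start, se$start + arr_len)
      bt <- bt[bt < arr_iv[1] | bt > arr_iv[2] + 0.6]
      big <- arr_iv[1] + cumsum(c(0.1, rep(c(0.32, 0.62), ceiling(arr_len))))
      big <- big[big <= arr_iv[2]]
      bt <- sort(c(bt, big))
      truth[[k]]$arr_start_s <- arr_iv[1]
      truth[[k]]$arr_stop_s <- arr_iv[2]
    }
    beats <- round(bt, 3)
    beats <- beats[c(TRUE, diff(beats) > 0.21)]
  }

  episode <- new_episode(
    newborn_id = id, outcome = "survived", birthweight_g = round(bw),
    ga_weeks = round(ga, 1), sex = sex, amniotic_fluid = amniotic,
    first_hr_bpm = round(first_hr), ventilated = ventilated,
    events = ev, hr = hr, beats = beats, duration_s = duration)
  attr(episode, "hr_noisefree") <- data.frame(t_s = t_s, hr_bpm = hr_noisefree)

  ## outcome drawn from truth labels (not detected labels)
  any_change <- n_se > 0 && any(vapply(se_list, function(s)
    s$label %in% c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA"),
    logical(1)))
  p_death <- if (any_change) sc$p_death_given_change else sc$p_death_given_no_change
  episode$outcome <- if (stats::runif(1) < p_death) "died_3d" else "survived"

  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    newborn_id = character(), se_index = integer(), truth_label = character(),
    se_start_s = numeric(), se_stop_s = numeric(), baseline_pre_bpm = numeric(),
    planted_fall_fraction = numeric(), planted_fall_bpm = numeric(),
    arr_start_s = numeric(), arr_stop_s = numeric(), stringsAsFactors = FALSE)
  list(episode = episode, truth = truth_df)
}

#' Generate a synthetic cohort
#'
#' Draws one episode per newborn. The master seed spawns one sub-seed per
#' newborn from a single stream, so any individual newborn is reproducible
#' independently of cohort size. Each newborn's death indicator is drawn
#' with probability `p_death_given_change` if at least one of its SE truths
#' is suction-related, else `p_death_given_no_change`.
#'
#' @param scenario An [scenario_config()].
#' @param out_dir Optional directory; if given, every episode is serialized
#'   via [write_episode()] and the truth table written as `truth.json`.
#' @return A list with `episodes` (list of `ns_episode`) and `truth`
#'   (row-bound truth `data.frame` across the cohort).
#' @export
#' @examples
#' coh <- generate_cohort(scenario_config(n_newborns = 3, seed = 42))
#' length(coh$episodes)
generate_cohort <- function(scenario, out_dir = NULL) {
  sc <- scenario
  if (!inherits(sc, "ns_scenario")) stop("scenario must be an ns_scenario")
  n <- as.integer(sc$n_newborns)
  set.seed(as.integer(sc$seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("nb%04d", seq_len(n))
  episodes <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_episode(sc, sub_seeds[i], ids[i])
    episodes[[i]] <- g$episode
    truths[[i]] <- g$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    for (ep in episodes) write_episode(ep, out_dir)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, dataframe = "rows")
  }
  list(episodes = episodes, truth = truth)
}

#' Simulate a second annotator's timeline
#'
#' Returns a perturbed copy of an episode's annotation timeline for
#' agreement testing: every interval boundary is jittered by centred
#' Gaussian noise and each event is independently dropped with probability
#' `p_miss`, except that at least one event is always retained.
#'
#' @param episode An `ns_episode` with a non-empty event table.
#' @param jitter_sd_s SD of the boundary jitter in seconds (>= 0).
#' @param p_miss Per-event drop probability in `[0, 1)`; values >= 1 are
#'   capped so that one event survives.
#' @param seed Integer seed.
#' @return An interval-event `data.frame`.
#' @export
generate_second_annotator <- function(episode, jitter_sd_s = 1, p_miss = 0.1,
                                      seed = 1L) {
  if (jitter_sd_s < 0) stop("jitter_sd_s must be >= 0")
  set.seed(as.integer(seed))
  ev <- episode$events
  if (!nrow(ev)) return(ev)
  keep <- stats::runif(nrow(ev)) >= p_miss
  if (!any(keep)) keep[sample.int(nrow(ev), 1)] <- TRUE
  ev <- ev[keep, , drop = FALSE]
  if (jitter_sd_s > 0) {
    ev$start_s <- pmax(ev$start_s + stats::rnorm(nrow(ev), 0, jitter_sd_s), 0)
    ev$stop_s <- pmin(ev$stop_s + stats::rnorm(nrow(ev), 0, jitter_sd_s),
                      episode$duration_s)
    bad <- ev$stop_s <= ev$start_s
    ev$stop_s[bad] <- ev$start_s[bad] + 0.2
  }
  ev <- ev[order(ev$start_s, ev$stop_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
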