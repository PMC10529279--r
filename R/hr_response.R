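## Pre/post heart-rate extraction and suction-event response classification.

#' Pre- and post-SE heart rate
#'
#' The heart rate before (after) a suction event is the median of the
#' `hr_samples_k` (default 5) HR samples nearest the SE boundary within
#' `hr_window_s` (default 20 s): pre from `[start - 20, start)`, post from
#' `(stop, stop + 20]`. If fewer than `hr_samples_k` but at least
#' `min_hr_samples` (default 3) samples are available, their median is used;
#' with fewer the value is missing (`NA`).
#'
#' @param hr `data.frame` with `t_s`, `hr_bpm`, time-sorted.
#' @param se One-row SE (anything with `start_s`, `stop_s`).
#' @param config An [analysis_config()].
#' @return Named numeric vector `c(pre = ..., post = ...)`, possibly `NA`.
#' @export
pre_post_hr <- function(hr, se, config = analysis_config()) {
  config <- as_config(config)
  k <- config$hr_samples_k
  m <- config$min_hr_samples
  w <- config$hr_window_s

  win_median <- function(idx, take_last) {
    n <- length(idx)
    if (n < m) return(NA_real_)
    if (n > k) idx <- if (take_last) idx[(n - k + 1L):n] else idx[1:k]
    stats::median(hr$hr_bpm[idx])
  }
  pre_idx <- which(hr$t_s >= se$start_s - w & hr$t_s < se$start_s & !is.na(hr$hr_bpm))
  post_idx <- which(hr$t_s > se$stop_s & hr$t_s <= se$stop_s + w & !is.na(hr$hr_bpm))
  c(pre = win_median(pre_idx, take_last = TRUE),
    post = win_median(post_idx, take_last = FALSE))
}

## consecutive runs of TRUE in a logical vector -> list of index ranges
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i], ends[i]))
}

#' Detect a suction-related heart-rate fall
#'
#' A fall is a run of at least `fall_min_samples` (default 2) consecutive HR
#' samples, during the SE or within `hr_window_s` after it
#' (`[start, stop + 20 s]`), lying strictly below
#' `pre_hr * (1 - fall_fraction)` (default: >15% below the pre-SE heart
#' rate), with no ventilation interval overlapping the excursion. The
#' deepest qualifying excursion is reported.
#'
#' @param hr HR stream (`t_s`, `hr_bpm`).
#' @param se One-row SE.
#' @param pre_hr Pre-SE heart rate in bpm (must be present).
#' @param ventilation_events Interval table of ventilation bouts (possibly
#'   empty).
#' @param config An [analysis_config()].
#' @return A list: `flag` (logical), `max_fall_fraction` (deepest qualifying
#'   relative fall, `NA` if none), `fall_interval` (`c(t_start, t_end)` of the
#'   deepest qualifying excursion, or `NULL`), and `observed_fall_fraction`
#'   (relative fall to the window minimum, regardless of qualification).
#' @export
detect_fall <- function(hr, se, pre_hr, ventilation_events,
                        config = analysis_config()) {
  config <- as_config(config)
  if (is.na(pre_hr)) stop("detect_fall requires a non-missing pre_hr")
  w_lo <- se$start_s
  w_hi <- se$stop_s + config$hr_window_s
  idx <- which(hr$t_s >= w_lo & hr$t_s <= w_hi & !is.na(hr$hr_bpm))
  none <- list(flag = FALSE, max_fall_fraction = NA_real_, fall_interval = NULL,
               observed_fall_fraction = NA_real_)
  if (!length(idx)) return(none)

  hrs <- hr$hr_bpm[idx]
  ts <- hr$t_s[idx]
  observed <- (pre_hr - min(hrs)) / pre_hr
  thr <- pre_hr * (1 - config$fall_fraction)
  runs <- true_runs(hrs < thr)
  runs <- Filter(function(r) (r[2] - r[1] + 1L) >= config$fall_min_samples, runs)

  vent <- ventilation_events
  vent_free <- function(r) {
    if (is.null(vent) || !nrow(vent)) return(TRUE)
    !any(overlaps(ts[r[1]], ts[r[2]], vent$start_s, vent$stop_s))
  }
  runs <- Filter(vent_free, runs)
  if (!length(runs)) {
    none$observed_fall_fraction <- observed
    return(none)
  }
  depths <- vapply(runs, function(r) (pre_hr - min(hrs[r[1]:r[2]])) / pre_hr,
                   numeric(1))
  best <- runs[[which.max(depths)]]
  list(flag = TRUE,
       max_fall_fraction = max(depths),
       fall_interval = c(ts[best[1]], ts[best[2]]),
       observed_fall_fraction = observed)
}

#' Detect bigeminy from beat times
#'
#' Flags bigeminy when a run of at least 8 beats intersecting
#' `[interval[1], interval[2]]` has strictly alternating short/long RR
#' intervals with a long/short ratio of at least 1.5 for every adjacent
#' pair. Fewer than 8 beats in the interval is insufficient evidence and
#' returns `FALSE` (never raises).
#'
#' @param beats Numeric vector of strictly increasing beat times (seconds),
#'   or `NULL`.
#' @param interval `c(t_start, t_end)` assessment window in seconds.
#' @param min_beats Minimum run length in beats (default 8).
#' @param ratio Minimum long/short RR ratio (default 1.5).
#' @return Logical flag.
#' @export
#' @examples
#' b <- cumsum(c(10, rep(c(0.3, 0.6), 5)))
#' detect_bigeminy(b, c(10, 16))  # TRUE
detect_bigeminy <- function(beats, interval, min_beats = 8, ratio = 1.5) {
  if (is.null(beats) || length(beats) < min_beats) return(FALSE)
  b <- beats[beats >= interval[1] & beats <= interval[2]]
  if (length(b) < min_beats) return(FALSE)
  rr <- diff(b)
  n_rr <- min_beats - 1L                       # RR intervals in a run of beats
  pair_ok <- vapply(seq_len(length(rr) - 1L), function(i) {
    hi <- max(rr[i], rr[i + 1L]); lo <- min(rr[i], rr[i + 1L])
    lo > 0 && hi / lo >= ratio
  }, logical(1))
  alt_ok <- c(TRUE, vapply(seq_len(length(rr) - 2L), function(i) {
    sign(rr[i + 1L] - rr[i]) * sign(rr[i + 2L] - rr[i + 1L]) < 0
  }, logical(1)))
  ok <- pair_ok & alt_ok
  runs <- true_runs(ok)
  any(vapply(runs, function(r) (r[2] - r[1] + 1L) >= n_rr - 1L, logical(1)))
}

#' Classify the HR response to one suction event
#'
#' Applies the classification rules in fixed precedence order:
#' \enumerate{
#'   \item pre- or post-SE HR missing and no arrhythmia detectable ->
#'     `INDETERMINATE`;
#'   \item a ventilation bout ends within `vent_cessation_gap_s` (default
#'     5 s) before SE start and HR falls by strictly more than
#'     `vent_cessation_fall_bpm` (default 30 bpm, absolute, vs pre-SE HR)
#'     during the SE or within 20 s after -> `VENT_CESSATION_FALL`
#'     (an HR change unrelated to suctioning);
#'   \item bigeminy overlapping the SE window -> `SUCTION_RELATED_ARRHYTHMIA`;
#'   \item a fall >15% of pre-SE HR absent concurrent ventilation ->
#'     `SUCTION_RELATED_FALL`;
#'   \item otherwise `NO_CHANGE`.
#' }
#' Ventilation-cessation precedes the suction-related checks because such
#' falls are attributed to interrupting ventilation, not to suctioning.
#'
#' @param episode The `ns_episode` (supplies HR, beats and ventilation /
#'   stimulation intervals).
#' @param se One-row SE from [merge_insertions()].
#' @param config An [analysis_config()].
#' @return One-row `data.frame` with `se_id`, `start_s`, `stop_s`,
#'   `duration_s`, `pre_hr_bpm`, `post_hr_bpm`, `delta_hr_bpm`,
#'   `fall_fraction_observed`, `label`, `concurrent_ventilation`,
#'   `ventilation_prior`, `stimulation_prior`, `device`, `n_insertions`,
#'   `n_mouth`, `n_nose`.
#' @export
classify_se <- function(episode, se, config = analysis_config()) {
  config <- as_config(config)
  hr <- episode$hr
  ev <- episode$events
  vent <- ev[ev$kind == "ventilation", , drop = FALSE]
  stim <- ev[ev$kind == "stimulation", , drop = FALSE]
  w <- config$hr_window_s

  pp <- pre_post_hr(hr, se, config)
  pre <- pp[["pre"]]; post <- pp[["post"]]

  win <- c(se$start_s, se$stop_s + w)
  arr <- detect_bigeminy(episode$beats, win)

  vent_prior <- nrow(vent) > 0 &&
    any(overlaps(se$start_s - w, se$start_s, vent$start_s, vent$stop_s))
  stim_prior <- nrow(stim) > 0 &&
    any(overlaps(se$start_s - w, se$start_s, stim$start_s, stim$stop_s))
  conc_vent <- nrow(vent) > 0 &&
    any(overlaps(se$start_s, se$stop_s + w, vent$start_s, vent$stop_s))

  fall_frac_obs <- NA_real_
  label <- NULL

  if ((is.na(pre) || is.na(post)) && !arr) {
    label <- "INDETERMINATE"
  } else if (is.na(pre) || is.na(post)) {
    label <- "SUCTION_RELATED_ARRHYTHMIA"
  } else {
    fall <- detect_fall(hr, se, pre, vent, config)
    fall_frac_obs <- fall$observed_fall_fraction

    vent_cease <- nrow(vent) > 0 &&
      any(vent$stop_s <= se$start_s &
            se$start_s - vent$stop_s <= config$vent_cessation_gap_s)
    if (vent_cease) {
      idx <- which(hr$t_s >= se$start_s & hr$t_s <= se$stop_s + w & !is.na(hr$hr_bpm))
      runs <- true_runs(hr$hr_bpm[idx] < pre - config$vent_cessation_fall_bpm)
      deep <- any(vapply(runs, function(r) (r[2] - r[1] + 1L) >= config$fall_min_samples,
                         logical(1)))
      if (deep) label <- "VENT_CESSATION_FALL"
    }
    if (is.null(label)) {
      if (arr) label <- "SUCTION_RELATED_ARRHYTHMIA"
      else if (fall$flag) label <- "SUCTION_RELATED_FALL"
      else label <- "NO_CHANGE"
    }
  }

  data.frame(
    se_id = se$se_id,
    start_s = se$start_s,
    stop_s = se$stop_s,
    duration_s = se$stop_s - se$start_s,
    pre_hr_bpm = pre,
    post_hr_bpm = post,
    delta_hr_bpm = if (!is.na(pre) && !is.na(post)) post - pre else NA_real_,
    fall_fraction_observed = fall_frac_obs,
    label = label,
    concurrent_ventilation = conc_vent,
    ventilation_prior = vent_prior,
    stimulation_prior = stim_prior,
    device = if (isTRUE(se$any_catheter)) "catheter" else if (isTRUE(se$any_bulb)) "bulb" else "unknown",
    n_insertions = se$n_insertions,
    n_mouth = se$n_mouth,
    n_nose = se$n_nose,
    stringsAsFactors = FALSE
  )
}

#' Classify every suction event in a cohort
#'
#' Runs segmentation ([merge_insertions()] + [clip_to_window()]) and
#' [classify_se()] over a list of episodes. Mirroring the complete-data
#' restriction of the source protocol, episodes whose responses are all
#' `INDETERMINATE` (no usable HR coverage) are excluded from the analysis
#' set; individual `INDETERMINATE` SEs in otherwise usable episodes are kept
#' in the table but carry no classification information.
#'
#' @param episodes List of `ns_episode` objects.
#' @param config An [analysis_config()].
#' @return A list with `responses` (analysis-set `data.frame`, one row per
#'   SE, with `newborn_id` and episode covariates joined), `any_change`
#'   (per-newborn `data.frame`: `newborn_id`, `outcome`, `n_se`,
#'   `any_suction_related`, `any_vent_cessation`), and `excluded`
#'   (`data.frame` log of excluded episodes with reasons).
#' @export
classify_cohort <- function(episodes, config = analysis_config()) {
  config <- as_config(config)
  resp_list <- list()
  excl <- data.frame(newborn_id = character(), reason = character(),
                     n_se = integer(), stringsAsFactors = FALSE)
  any_change <- list()

  for (ep in episodes) {
    ins <- ep$events[ep$events$kind == "suction_insertion", , drop = FALSE]
    ses <- clip_to_window(merge_insertions(ins, config), config)
    if (!nrow(ses)) next
    rows <- do.call(rbind, lapply(seq_len(nrow(ses)), function(i)
      classify_se(ep, ses[i, , drop = FALSE], config)))
    rows <- cbind(newborn_id = ep$newborn_id, rows,
                  outcome = ep$outcome, sex = ep$sex,
                  amniotic_fluid = ep$amniotic_fluid,
                  birthweight_g = ep$birthweight_g, ga_weeks = ep$ga_weeks,
                  first_hr_bpm = ep$first_hr_bpm,
                  stringsAsFactors = FALSE)
    if (all(rows$label == "INDETERMINATE")) {
      excl <- rbind(excl, data.frame(
        newborn_id = ep$newborn_id,
        reason = "no usable HR coverage: all SE responses indeterminate",
        n_se = nrow(rows), stringsAsFactors = FALSE))
      next
    }
    resp_list[[length(resp_list) + 1L]] <- rows
    any_change[[length(any_change) + 1L]] <- data.frame(
      newborn_id = ep$newborn_id, outcome = ep$outcome, n_se = nrow(rows),
      any_suction_related = any(rows$label %in%
        c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA")),
      any_vent_cessation = any(rows$label == "VENT_CESSATION_FALL"),
      stringsAsFactors = FALSE)
  }
  responses <- if (length(resp_list)) do.call(rbind, resp_list) else
    data.frame()
  rownames(responses) <- NULL
  list(responses = responses,
       any_change = if (length(any_change)) do.call(rbind, any_change) else
         data.frame(),
       excluded = excl)
}
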