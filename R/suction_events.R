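## Suction-event segmentation and per-newborn suction summaries.

#' Merge suction insertions into suction events
#'
#' One suction event (SE) is a period of repetitive suctioning with no pause
#' greater than `max_pause_s` (default 5 s) between consecutive insertions;
#' a pause strictly greater than that starts a new SE. The pause is measured
#' stop-to-start between consecutive insertions (idle time), so a pause of
#' exactly 5 s does not split.
#'
#' Overlapping insertions from a single annotator are first merged into one
#' insertion (their union) with a warning, keeping the first insertion's site
#' and device.
#'
#' @param insertions `data.frame` of interval events, all with
#'   `kind == "suction_insertion"` (any order).
#' @param config An [analysis_config()].
#' @return A `data.frame` with one row per SE, sorted and non-overlapping:
#'   columns `se_id`, `start_s`, `stop_s`, `duration_s`, `n_insertions`,
#'   `n_mouth`, `n_nose`, `n_site_unknown`, `any_catheter`, `any_bulb`,
#'   `devices` (comma-joined), plus a list-column `insertions` holding each
#'   SE's member insertions.
#' @export
#' @examples
#' ins <- interval_events(kind = rep("suction_insertion", 2),
#'                        start_s = c(0, 9), stop_s = c(3, 12),
#'                        site = "mouth", device = "bulb")
#' merge_insertions(ins, analysis_config())  # gap 6 s > 5 s: two SEs
merge_insertions <- function(insertions, config = analysis_config()) {
  config <- as_config(config)
  empty <- data.frame(
    se_id = integer(), start_s = numeric(), stop_s = numeric(),
    duration_s = numeric(), n_insertions = integer(), n_mouth = integer(),
    n_nose = integer(), n_site_unknown = integer(), any_catheter = logical(),
    any_bulb = logical(), devices = character(), stringsAsFactors = FALSE)
  empty$insertions <- list()
  if (is.null(insertions) || !nrow(insertions)) return(empty)
  if (any(insertions$kind != "suction_insertion"))
    stop("merge_insertions expects only suction_insertion events")

  ins <- insertions[order(insertions$start_s, insertions$stop_s), , drop = FALSE]

  # collapse overlapping insertions (annotation slip) into their union
  keep <- ins[1L, , drop = FALSE]
  merged_any <- FALSE
  if (nrow(ins) > 1L) {
    for (i in 2:nrow(ins)) {
      last <- nrow(keep)
      if (ins$start_s[i] < keep$stop_s[last]) {
        keep$stop_s[last] <- max(keep$stop_s[last], ins$stop_s[i])
        merged_any <- TRUE
      } else {
        keep <- rbind(keep, ins[i, , drop = FALSE])
      }
    }
  }
  if (merged_any)
    warning("overlapping suction insertions merged into one insertion")
  ins <- keep

  gap <- c(Inf, ins$start_s[-1L] - ins$stop_s[-nrow(ins)])
  se_id <- cumsum(gap > config$max_pause_s)

  groups <- split(seq_len(nrow(ins)), se_id)
  out <- lapply(seq_along(groups), function(g) {
    sub <- ins[groups[[g]], , drop = FALSE]
    data.frame(
      se_id = g,
      start_s = min(sub$start_s),
      stop_s = max(sub$stop_s),
      duration_s = max(sub$stop_s) - min(sub$start_s),
      n_insertions = nrow(sub),
      n_mouth = sum(sub$site == "mouth", na.rm = TRUE),
      n_nose = sum(sub$site == "nose", na.rm = TRUE),
      n_site_unknown = sum(is.na(sub$site) | sub$site == "unknown"),
      any_catheter = any(sub$device == "catheter", na.rm = TRUE),
      any_bulb = any(sub$device == "bulb", na.rm = TRUE),
      devices = paste(sort(unique(stats::na.omit(sub$device))), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res$insertions <- lapply(groups, function(idx) ins[idx, , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Clip suction events to the analysis window
#'
#' Suction annotations are analysed within a limited timeframe
#' (`analysis_window_s`, default 420 s after birth). Events are intersected
#' with `[0, analysis_window_s)`: an SE straddling the boundary is truncated,
#' an SE entirely beyond it is dropped, and its member insertions are clipped
#' the same way (counts are recomputed). `analysis_window_s = Inf` leaves the
#' input unchanged.
#'
#' @param ses SE table from [merge_insertions()].
#' @param config An [analysis_config()].
#' @return Clipped SE table with `se_id` renumbered from 1.
#' @export
clip_to_window <- function(ses, config = analysis_config()) {
  config <- as_config(config)
  w <- config$analysis_window_s
  if (!nrow(ses) || is.infinite(w)) return(ses)
  keep <- ses$start_s < w
  ses <- ses[keep, , drop = FALSE]
  if (!nrow(ses)) {
    ses$se_id <- integer(0)
    return(ses)
  }
  for (i in seq_len(nrow(ses))) {
    if (ses$stop_s[i] > w) ses$stop_s[i] <- w
    sub <- ses$insertions[[i]]
    sub <- sub[sub$start_s < w, , drop = FALSE]
    sub$stop_s <- pmin(sub$stop_s, w)
    ses$insertions[[i]] <- sub
    ses$n_insertions[i] <- nrow(sub)
    ses$n_mouth[i] <- sum(sub$site == "mouth", na.rm = TRUE)
    ses$n_nose[i] <- sum(sub$site == "nose", na.rm = TRUE)
    ses$n_site_unknown[i] <- sum(is.na(sub$site) | sub$site == "unknown")
    ses$any_catheter[i] <- any(sub$device == "catheter", na.rm = TRUE)
    ses$any_bulb[i] <- any(sub$device == "bulb", na.rm = TRUE)
    ses$devices[i] <- paste(sort(unique(stats::na.omit(sub$device))), collapse = ",")
  }
  ses$duration_s <- ses$stop_s - ses$start_s
  ses$se_id <- seq_len(nrow(ses))
  rownames(ses) <- NULL
  ses
}

#' Per-newborn suction summary
#'
#' Aggregates an episode's suction events into the descriptive quantities
#' reported per newborn: number of SEs, total and proportional suctioning
#' time within the analysed window, insertion counts by site, mean
#' insertions per SE, and catheter use.
#'
#' @param episode The `ns_episode` the SEs were derived from.
#' @param ses SE table (after [clip_to_window()]).
#' @param config An [analysis_config()].
#' @return A one-row `data.frame` with columns `newborn_id`, `n_se`,
#'   `total_suction_s`, `proportion_time_suctioning`, `n_insertions`,
#'   `n_mouth`, `n_nose`, `n_site_unknown`, `insertions_per_se`,
#'   `any_catheter`, `analyzed_window_s`.
#' @export
summarize_suction <- function(episode, ses, config = analysis_config()) {
  config <- as_config(config)
  window <- min(episode$duration_s, config$analysis_window_s)
  n_se <- nrow(ses)
  total <- if (n_se) sum(ses$duration_s) else 0
  n_ins <- if (n_se) sum(ses$n_insertions) else 0L
  data.frame(
    newborn_id = episode$newborn_id,
    n_se = n_se,
    total_suction_s = total,
    proportion_time_suctioning = if (window > 0) total / window else NA_real_,
    n_insertions = n_ins,
    n_mouth = if (n_se) sum(ses$n_mouth) else 0L,
    n_nose = if (n_se) sum(ses$n_nose) else 0L,
    n_site_unknown = if (n_se) sum(ses$n_site_unknown) else 0L,
    insertions_per_se = if (n_se) n_ins / n_se else NA_real_,
    any_catheter = if (n_se) any(ses$any_catheter) else FALSE,
    analyzed_window_s = window,
    stringsAsFactors = FALSE
  )
}

#' Inter-annotator agreement over an episode timeline
#'
#' Computes the fraction of `[0, episode_duration_s)` during which two
#' annotators' label sets -- the set of event kinds active at each instant --
#' are identical. Time where both annotators mark nothing counts as
#' agreement. An episode is flagged for consensus review when the score
#' falls below `agreement_threshold` (default 0.80).
#'
#' The published protocol states only that annotations had to "match" over
#' the episode; a time-in-agreement metric is the one computable from
#' interval data alone and is used here (see the package vignette).
#'
#' @param timeline_a,timeline_b Interval-event tables for the same episode.
#' @param episode_duration_s Positive episode duration in seconds.
#' @param config An [analysis_config()] (supplies the review threshold).
#' @return A list with `score` (proportion in `[0, 1]`) and `flagged`
#'   (logical, `TRUE` if below threshold).
#' @export
#' @examples
#' a <- interval_events("suction_insertion", 0, 10, "mouth", "bulb")
#' b <- interval_events("suction_insertion", 0, 8, "mouth", "bulb")
#' agreement_score(a, b, 100)$score  # 0.98
agreement_score <- function(timeline_a, timeline_b, episode_duration_s,
                            config = analysis_config()) {
  config <- as_config(config)
  if (!is.numeric(episode_duration_s) || episode_duration_s <= 0)
    stop("episode_duration_s must be positive")
  d <- episode_duration_s
  cuts <- sort(unique(c(0, d,
                        pmin(pmax(c(timeline_a$start_s, timeline_a$stop_s,
                                    timeline_b$start_s, timeline_b$stop_s), 0), d))))
  active_kinds <- function(tl, t) {
    if (!nrow(tl)) return(character())
    sort(unique(tl$kind[tl$start_s <= t & t < tl$stop_s]))
  }
  agree_t <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    mid <- (cuts[i] + cuts[i + 1L]) / 2
    if (identical(active_kinds(timeline_a, mid), active_kinds(timeline_b, mid)))
      agree_t <- agree_t + (cuts[i + 1L] - cuts[i])
  }
  score <- agree_t / d
  list(score = score, flagged = score < config$agreement_threshold)
}
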