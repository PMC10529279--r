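## Domain containers for one resuscitation episode.
##
## Conventions: the time origin is birth, all times are non-negative seconds,
## and intervals are half-open [start, stop) so that an event ending at t and
## another starting at t do not overlap.

EVENT_KINDS <- c("suction_insertion", "ventilation", "stimulation", "covering")
SITES <- c("mouth", "nose", "unknown")
DEVICES <- c("bulb", "catheter", "unknown")
OUTCOMES <- c("died_3d", "survived")
SEXES <- c("female", "male")
AMNIOTIC <- c("clear", "slight", "thick_blood")
SE_LABELS <- c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA",
               "VENT_CESSATION_FALL", "NO_CHANGE", "INDETERMINATE")

#' Construct an interval-event table
#'
#' Builds the typed annotation timeline of an episode: suction insertions
#' (with site and device), ventilation bouts, stimulation and covering, each
#' as a half-open interval `[start_s, stop_s)` in seconds since birth.
#'
#' @param kind Character vector; one of `"suction_insertion"`,
#'   `"ventilation"`, `"stimulation"`, `"covering"`.
#' @param start_s,stop_s Numeric vectors of interval boundaries in seconds.
#' @param site Suction site, `"mouth"`, `"nose"` or `"unknown"`; `NA` for
#'   non-suction events.
#' @param device Suction device, `"bulb"`, `"catheter"` or `"unknown"`; `NA`
#'   for non-suction events.
#' @param obscured Logical; whether the camera view of the intervention was
#'   obscured.
#' @return A `data.frame` with one row per event, sorted by `start_s`.
#' @export
#' @examples
#' interval_events(kind = c("suction_insertion", "ventilation"),
#'                 start_s = c(30, 10), stop_s = c(33, 25),
#'                 site = c("mouth", NA), device = c("bulb", NA))
interval_events <- function(kind = character(), start_s = numeric(),
                            stop_s = numeric(), site = NA_character_,
                            device = NA_character_, obscured = FALSE) {
  n <- length(kind)
  ev <- data.frame(
    kind = as.character(kind),
    start_s = as.numeric(start_s),
    stop_s = as.numeric(stop_s),
    site = rep_len(as.character(site), n),
    device = rep_len(as.character(device), n),
    obscured = rep_len(as.logical(obscured), n),
    stringsAsFactors = FALSE
  )
  ev[order(ev$start_s, ev$stop_s), , drop = FALSE]
}

#' Construct a resuscitation episode
#'
#' Bundles one newborn's annotation timeline, monitor-derived heart-rate
#' stream, optional beat-time series and covariates into a single record.
#'
#' @param newborn_id Identifier string.
#' @param outcome `"died_3d"` or `"survived"`.
#' @param birthweight_g Birthweight in grams.
#' @param ga_weeks Gestational age in completed weeks (study population is
#'   liveborn newborns at >= 34 weeks).
#' @param sex `"female"` or `"male"`.
#' @param amniotic_fluid `"clear"`, `"slight"` or `"thick_blood"` (thick
#'   meconium and blood-stained are collapsed into one category, as is done
#'   for regression analysis).
#' @param first_hr_bpm First observed heart rate after birth, bpm.
#' @param ventilated Logical; whether the newborn received bag-mask
#'   ventilation.
#' @param events Interval-event table, see [interval_events()].
#' @param hr `data.frame` with columns `t_s`, `hr_bpm`: the ~1 Hz heart-rate
#'   stream (strictly increasing `t_s`, gaps allowed).
#' @param beats Optional numeric vector of strictly increasing beat times in
#'   seconds (for arrhythmia detection from RR intervals), or `NULL`.
#' @param duration_s Episode duration in seconds.
#' @return An object of class `ns_episode`.
#' @export
new_episode <- function(newborn_id, outcome, birthweight_g, ga_weeks, sex,
                        amniotic_fluid, first_hr_bpm, ventilated,
                        events, hr, beats = NULL, duration_s) {
  structure(list(
    newborn_id = as.character(newborn_id),
    outcome = as.character(outcome),
    birthweight_g = as.numeric(birthweight_g),
    ga_weeks = as.numeric(ga_weeks),
    sex = as.character(sex),
    amniotic_fluid = as.character(amniotic_fluid),
    first_hr_bpm = as.numeric(first_hr_bpm),
    ventilated = as.logical(ventilated),
    events = events,
    hr = hr,
    beats = if (is.null(beats)) NULL else as.numeric(beats),
    duration_s = as.numeric(duration_s)
  ), class = "ns_episode")
}

#' @export
print.ns_episode <- function(x, ...) {
  cat(sprintf("<ns_episode %s> outcome=%s, %.0f s, %d events, %d HR samples%s\n",
              x$newborn_id, x$outcome, x$duration_s, nrow(x$events),
              nrow(x$hr),
              if (is.null(x$beats)) "" else sprintf(", %d beats", length(x$beats))))
  invisible(x)
}

#' Validate an episode record
#'
#' Checks every structural invariant of an episode and reports violations as
#' messages instead of raising, so that a whole cohort can be screened. The
#' function is pure: it never mutates its input.
#'
#' @param episode An `ns_episode`.
#' @return Character vector of violation messages; empty if the episode is
#'   well formed.
#' @export
#' @examples
#' ep <- new_episode("b1", "survived", 3100, 38, "male", "clear", 120, TRUE,
#'                   interval_events(), data.frame(t_s = 1:3, hr_bpm = c(120, 121, 122)),
#'                   duration_s = 300)
#' validate_episode(ep)  # character(0)
validate_episode <- function(episode) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  e <- episode

  if (!length(e$newborn_id) || is.na(e$newborn_id) || !nzchar(e$newborn_id))
    add("newborn_id is missing")
  if (!e$outcome %in% OUTCOMES)
    add(sprintf("outcome '%s' not one of {%s}", e$outcome, paste(OUTCOMES, collapse = ", ")))
  if (!is.na(e$birthweight_g) && (e$birthweight_g < 1000 || e$birthweight_g > 6000))
    add(sprintf("birthweight_g %.0f outside plausible range [1000, 6000]", e$birthweight_g))
  if (!is.na(e$ga_weeks) && e$ga_weeks < 34)
    add(sprintf("ga_weeks %.1f below study minimum of 34", e$ga_weeks))
  if (!e$sex %in% SEXES) add(sprintf("sex '%s' unknown", e$sex))
  if (!e$amniotic_fluid %in% AMNIOTIC)
    add(sprintf("amniotic_fluid '%s' unknown", e$amniotic_fluid))
  if (!is.na(e$first_hr_bpm) && (e$first_hr_bpm <= 0 || e$first_hr_bpm > 300))
    add(sprintf("first_hr_bpm %.1f outside (0, 300]", e$first_hr_bpm))
  if (is.na(e$duration_s) || e$duration_s <= 0)
    add("duration_s must be positive")

  ev <- e$events
  if (nrow(ev)) {
    bad_kind <- !ev$kind %in% EVENT_KINDS
    for (i in which(bad_kind))
      add(sprintf("event %d: unknown kind '%s'", i, ev$kind[i]))
    bad_iv <- !is.na(ev$start_s) & !is.na(ev$stop_s) &
      (ev$start_s < 0 | ev$stop_s <= ev$start_s)
    for (i in which(bad_iv))
      add(sprintf("event %d (%s): invalid interval [%g, %g)", i, ev$kind[i],
                  ev$start_s[i], ev$stop_s[i]))
    is_suction <- ev$kind == "suction_insertion"
    for (i in which(is_suction & !(ev$site %in% SITES)))
      add(sprintf("event %d: suction site '%s' unknown", i, ev$site[i]))
    for (i in which(is_suction & !(ev$device %in% DEVICES)))
      add(sprintf("event %d: suction device '%s' unknown", i, ev$device[i]))
    for (i in which(!is_suction & (!is.na(ev$site) | !is.na(ev$device))))
      add(sprintf("event %d (%s): site/device set on a non-suction event", i, ev$kind[i]))
  }

  hr <- e$hr
  if (nrow(hr)) {
    if (any(diff(hr$t_s) <= 0)) {
      i <- which(diff(hr$t_s) <= 0)[1L]
      add(sprintf("hr series: t_s not strictly increasing at sample %d (t = %g)",
                  i + 1L, hr$t_s[i + 1L]))
    }
    if (any(hr$hr_bpm <= 0 | hr$hr_bpm > 300, na.rm = TRUE))
      add("hr series: hr_bpm values outside (0, 300]")
  }

  if (!is.null(e$beats) && length(e$beats) > 1L) {
    rr <- diff(e$beats)
    if (any(rr <= 0))
      add("beats: beat times not strictly increasing")
    else if (any(rr <= 0.2 | rr >= 3))
      add("beats: RR intervals outside (0.2, 3) s")
  }
  v
}

## ---- File I/O ---------------------------------------------------------
## Layout: <id>_events.csv (kind,start_s,stop_s,site,device,obscured),
## <id>_hr.csv (t_s,hr_bpm), <id>_episode.json (covariates + beats).

#' Write an episode to disk
#'
#' Serializes one episode as the file triple
#' `<id>_events.csv`, `<id>_hr.csv`, `<id>_episode.json` in `dir`.
#' CSV is RFC 4180 UTF-8 with '.' decimal separator; the JSON file carries
#' covariates, duration, and the optional beat-time vector.
#'
#' @param episode An `ns_episode`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the character vector of the three file paths.
#' @export
write_episode <- function(episode, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- episode$newborn_id
  p_ev <- file.path(dir, paste0(id, "_events.csv"))
  p_hr <- file.path(dir, paste0(id, "_hr.csv"))
  p_js <- file.path(dir, paste0(id, "_episode.json"))
  utils::write.csv(episode$events, p_ev, row.names = FALSE, na = "")
  utils::write.csv(episode$hr, p_hr, row.names = FALSE, na = "")
  meta <- list(
    newborn_id = episode$newborn_id,
    outcome = episode$outcome,
    birthweight_g = episode$birthweight_g,
    ga_weeks = episode$ga_weeks,
    sex = episode$sex,
    amniotic_fluid = episode$amniotic_fluid,
    first_hr_bpm = episode$first_hr_bpm,
    ventilated = episode$ventilated,
    duration_s = episode$duration_s,
    beats = episode$beats
  )
  jsonlite::write_json(meta, p_js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(events = p_ev, hr = p_hr, episode = p_js))
}

read_typed_csv <- function(path, spec_cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = NA)
  missing_cols <- setdiff(names(spec_cols), names(df))
  if (length(missing_cols))
    stop(sprintf("%s (%s): missing column(s) %s", what, basename(path),
                 paste(missing_cols, collapse = ", ")))
  for (col in names(spec_cols)) {
    if (spec_cols[[col]] == "numeric") {
      raw <- df[[col]]
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & !is.na(raw))
      if (length(bad))
        stop(sprintf("%s (%s): unparseable number '%s' in column '%s', row %d",
                     what, basename(path), raw[bad[1L]], col, bad[1L]))
      df[[col]] <- num
    }
  }
  df
}

#' Read an episode from disk
#'
#' Inverse of [write_episode()]: `read_episode(dir, id)` reconstructs the
#' episode from its file triple. Round-trip is lossless field for field.
#' Parse failures (missing column, unparseable number, unknown enum value)
#' raise an error naming the file, column and row.
#'
#' @param dir Directory containing the episode files.
#' @param id Newborn identifier (file-name prefix).
#' @return An `ns_episode`.
#' @export
read_episode <- function(dir, id) {
  p_ev <- file.path(dir, paste0(id, "_events.csv"))
  p_hr <- file.path(dir, paste0(id, "_hr.csv"))
  p_js <- file.path(dir, paste0(id, "_episode.json"))
  for (p in c(p_ev, p_hr, p_js))
    if (!file.exists(p)) stop(sprintf("episode file not found: %s", p))

  ev <- read_typed_csv(p_ev, c(kind = "character", start_s = "numeric",
                               stop_s = "numeric", site = "character",
                               device = "character"), "events.csv")
  if (!"obscured" %in% names(ev)) ev$obscured <- FALSE
  ev$obscured <- as.logical(ev$obscured)
  ev$obscured[is.na(ev$obscured)] <- FALSE
  for (col in c("kind", "site", "device"))  # all-NA columns parse as logical
    ev[[col]] <- as.character(ev[[col]])
  bad <- which(!ev$kind %in% EVENT_KINDS)
  if (length(bad))
    stop(sprintf("events.csv (%s): unknown event kind '%s' in row %d",
                 basename(p_ev), ev$kind[bad[1L]], bad[1L]))
  bad <- which(ev$kind == "suction_insertion" & !is.na(ev$site) & !ev$site %in% SITES)
  if (length(bad))
    stop(sprintf("events.csv (%s): unknown site '%s' in row %d",
                 basename(p_ev), ev$site[bad[1L]], bad[1L]))
  bad <- which(ev$kind == "suction_insertion" & !is.na(ev$device) & !ev$device %in% DEVICES)
  if (length(bad))
    stop(sprintf("events.csv (%s): unknown device '%s' in row %d",
                 basename(p_ev), ev$device[bad[1L]], bad[1L]))
  ev <- ev[, c("kind", "start_s", "stop_s", "site", "device", "obscured")]

  hr <- read_typed_csv(p_hr, c(t_s = "numeric", hr_bpm = "numeric"), "hr.csv")
  hr <- hr[, c("t_s", "hr_bpm")]

  meta <- jsonlite::read_json(p_js, simplifyVector = TRUE)
  if (!meta$outcome %in% OUTCOMES)
    stop(sprintf("episode.json (%s): unknown outcome '%s'", basename(p_js), meta$outcome))
  new_episode(
    newborn_id = meta$newborn_id, outcome = meta$outcome,
    birthweight_g = meta$birthweight_g, ga_weeks = meta$ga_weeks,
    sex = meta$sex, amniotic_fluid = meta$amniotic_fluid,
    first_hr_bpm = meta$first_hr_bpm, ventilated = meta$ventilated,
    events = ev, hr = hr,
    beats = if (is.null(meta$beats) || !length(meta$beats)) NULL else meta$beats,
    duration_s = meta$duration_s
  )
}

#' List episode identifiers present in a directory
#'
#' @param dir Directory holding `<id>_episode.json` files.
#' @return Character vector of ids (possibly empty).
#' @export
list_episode_ids <- function(dir) {
  files <- list.files(dir, pattern = "_episode\\.json$")
  sort(sub("_episode\\.json$", "", files))
}

## half-open interval overlap: [a1,a2) vs [b1,b2)
overlaps <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2
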