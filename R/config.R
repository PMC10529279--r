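#' Analysis configuration
#'
#' All thresholds used by the suction-event and heart-rate-response pipeline
#' live in one object so that every operation takes them explicitly and
#' sensitivity analyses only have to change a single place. The defaults are
#' the study's fixed cutoffs; the last three arguments are implementation
#' parameters with no counterpart in the clinical protocol.
#'
#' @param max_pause_s Maximum pause, in seconds, between consecutive suction
#'   insertions that still belong to the same suction event (SE). A pause
#'   strictly greater than this splits the run into two SEs. Default 5.
#' @param hr_window_s Half-width, in seconds, of the heart-rate assessment
#'   windows: pre-SE HR is taken from up to this many seconds before SE
#'   start, post-SE HR from up to this many seconds after SE stop, and falls
#'   are searched for during the SE and up to this many seconds after it.
#'   Default 20.
#' @param hr_samples_k Number of HR samples whose median defines the pre- and
#'   post-SE heart rate. Default 5.
#' @param fall_fraction A suction-related fall requires HR to drop by strictly
#'   more than this fraction of the pre-SE heart rate. Default 0.15.
#' @param vent_cessation_fall_bpm Absolute HR drop, in bpm, that qualifies a
#'   fall following cessation of positive-pressure ventilation as a
#'   ventilation-cessation fall (classified as unrelated to suctioning).
#'   Strictly-greater-than rule. Default 30.
#' @param vent_cessation_gap_s A ventilation bout ending at most this many
#'   seconds before SE start counts as ceasing "immediately prior" to the SE.
#'   Default 5, matching the intervention-pause convention.
#' @param analysis_window_s Length, in seconds since birth, of the window
#'   within which suction annotations are analysed; events are clipped to
#'   `[0, analysis_window_s)`. Default 420. Use `Inf` to disable clipping.
#' @param agreement_threshold Minimum inter-annotator time-in-agreement
#'   proportion below which an episode is flagged for consensus review.
#'   Default 0.80.
#' @param min_hr_samples Minimum number of samples in a pre/post window for
#'   the median to be considered usable; fewer yields a missing value.
#'   Default 3.
#' @param fall_min_samples Minimum number of consecutive sub-threshold HR
#'   samples required before an excursion counts as a fall (a single noisy
#'   sample is not a fall). Default 2.
#'
#' @return An object of class `ns_config`: a validated named list.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$max_pause_s
analysis_config <- function(max_pause_s = 5,
                            hr_window_s = 20,
                            hr_samples_k = 5,
                            fall_fraction = 0.15,
                            vent_cessation_fall_bpm = 30,
                            vent_cessation_gap_s = 5,
                            analysis_window_s = 420,
                            agreement_threshold = 0.80,
                            min_hr_samples = 3,
                            fall_min_samples = 2) {
  cfg <- list(
    max_pause_s = max_pause_s,
    hr_window_s = hr_window_s,
    hr_samples_k = hr_samples_k,
    fall_fraction = fall_fraction,
    vent_cessation_fall_bpm = vent_cessation_fall_bpm,
    vent_cessation_gap_s = vent_cessation_gap_s,
    analysis_window_s = analysis_window_s,
    agreement_threshold = agreement_threshold,
    min_hr_samples = min_hr_samples,
    fall_min_samples = fall_min_samples
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config field '%s' must be a single positive number", nm))
  }
  if (cfg$fall_fraction >= 1)
    stop("fall_fraction must lie in (0, 1)")
  if (cfg$agreement_threshold > 1)
    stop("agreement_threshold must lie in (0, 1]")
  if (cfg$hr_samples_k < cfg$min_hr_samples)
    stop("hr_samples_k must be >= min_hr_samples")
  structure(cfg, class = "ns_config")
}

#' @export
print.ns_config <- function(x, ...) {
  cat("<neosuction analysis configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_config <- function(config) {
  if (inherits(config, "ns_config")) return(config)
  if (is.list(config)) return(do.call(analysis_config, config))
  stop("'config' must be an ns_config object (see analysis_config())")
}
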