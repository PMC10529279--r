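## End-to-end orchestration and report assembly.

fmt_pct <- function(num, den) {
  if (den == 0) return(NA_character_)
  sprintf("%.1f%%", 100 * num / den)
}

#' Assemble the analysis report
#'
#' Renders per-group (died vs survived) suction summaries, SE response
#' classification counts with percentages, the 2x2 mortality comparisons
#' (any suction-related change x died, and any ventilation-cessation fall x
#' died) with Pearson chi-square, and the predictor-screen table, as a list
#' (JSON-ready) plus Markdown lines. All percentages are recomputed from
#' the counts carried in the same report. If no suction-related changes
#' were detected, the mortality comparison is replaced by a "not estimable"
#' note.
#'
#' @param summaries Row-bound [summarize_suction()] output for the cohort.
#' @param classified Result of [classify_cohort()].
#' @param screen Optional [predictor_screen()] table (or `NULL`).
#' @return A list of class `ns_report` with elements `suction`, `labels`,
#'   `mortality`, `screen`, `markdown`.
#' @export
make_report <- function(summaries, classified, screen = NULL) {
  resp <- classified$responses
  per_baby <- classified$any_change
  md <- character()

  ## --- suction descriptives by outcome group ---
  suction <- list()
  md <- c(md, "# Suctioning during resuscitation", "")
  outcome_of <- if (nrow(per_baby))
    stats::setNames(per_baby$outcome, per_baby$newborn_id) else character()
  for (grp in list(c("all", OUTCOMES), c("died_3d", "died_3d"),
                   c("survived", "survived"))) {
    nm <- grp[1]; levels_keep <- grp[-1]
    sel <- summaries
    if (nm != "all" && nrow(per_baby))
      sel <- summaries[summaries$newborn_id %in%
                         per_baby$newborn_id[per_baby$outcome %in% levels_keep], ,
                       drop = FALSE]
    if (!nrow(sel)) next
    suction[[nm]] <- list(
      n_babies = nrow(sel),
      n_with_se = sum(sel$n_se > 0),
      n_se = summarize_repeated(sel$n_se),
      total_suction_s = summarize_repeated(sel$total_suction_s),
      proportion_time = summarize_repeated(sel$proportion_time_suctioning),
      insertions_per_se = if (any(sel$n_se > 0))
        summarize_repeated(sel$insertions_per_se[sel$n_se > 0]) else NULL,
      any_catheter = sum(sel$any_catheter)
    )
    md <- c(md, sprintf("- %s: %d babies, %d (%s) with at least one SE",
                        nm, nrow(sel), sum(sel$n_se > 0),
                        fmt_pct(sum(sel$n_se > 0), nrow(sel))))
  }

  ## --- SE label counts ---
  md <- c(md, "", "# Suction-event responses", "")
  labels <- list(counts = list(), pct = list(), n_se = nrow(resp))
  if (nrow(resp)) {
    tab <- table(factor(resp$label, levels = SE_LABELS))
    for (l in names(tab)) {
      labels$counts[[l]] <- unname(tab[[l]])
      labels$pct[[l]] <- round(100 * tab[[l]] / nrow(resp), 1)
      md <- c(md, sprintf("- %s: %d (%s)", l, tab[[l]],
                          fmt_pct(tab[[l]], nrow(resp))))
    }
  }

  ## --- mortality 2x2 comparisons ---
  md <- c(md, "", "# Mortality comparisons", "")
  mortality <- list()
  mk_2x2 <- function(flag_col, name) {
    flag <- per_baby[[flag_col]]
    died <- per_baby$outcome == "died_3d"
    tab <- matrix(c(sum(flag & died), sum(flag & !died),
                    sum(!flag & died), sum(!flag & !died)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("change", "no_change"),
                                  c("died", "survived")))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chi <- chi2_2x2(tab)
      list(table = tab, estimable = TRUE,
           died_pct_change = round(100 * tab[1, 1] / sum(tab[1, ]), 1),
           died_pct_no_change = round(100 * tab[2, 1] / sum(tab[2, ]), 1),
           statistic = chi$statistic, p = chi$p)
    } else {
      list(table = tab, estimable = FALSE,
           note = sprintf("%s: not estimable (empty margin)", name))
    }
  }
  if (nrow(per_baby)) {
    mortality$suction_related <- mk_2x2("any_suction_related",
                                        "suction-related change vs death")
    mortality$vent_cessation <- mk_2x2("any_vent_cessation",
                                       "ventilation-cessation fall vs death")
    for (nm in names(mortality)) {
      m <- mortality[[nm]]
      if (m$estimable) {
        md <- c(md, sprintf(
          "- %s: died %d/%d (%s) with change vs %d/%d (%s) without; chi2 = %.2f, p = %.3f",
          nm, m$table[1, 1], sum(m$table[1, ]),
          fmt_pct(m$table[1, 1], sum(m$table[1, ])),
          m$table[2, 1], sum(m$table[2, ]),
          fmt_pct(m$table[2, 1], sum(m$table[2, ])),
          m$statistic, m$p))
      } else md <- c(md, paste0("- ", m$note))
    }
  }

  ## --- predictor screen ---
  if (!is.null(screen)) {
    md <- c(md, "", "# Predictor screen", "",
            "predictor | level | OR | 95% CI | p | p_NL",
            "--- | --- | --- | --- | --- | ---")
    for (i in seq_len(nrow(screen))) {
      s <- screen[i, ]
      md <- c(md, sprintf("%s | %s | %s | %s | %.3g | %s",
                          s$predictor, s$level,
                          if (is.na(s$or)) "-" else sprintf("%.2f", s$or),
                          if (is.na(s$or)) "-" else
                            sprintf("%.2f-%.2f", s$ci_lo, s$ci_hi),
                          s$p,
                          if (is.na(s$p_nl)) "-" else sprintf("%.3g", s$p_nl)))
    }
  }

  structure(list(suction = suction, labels = labels, mortality = mortality,
                 screen = screen, markdown = md),
            class = "ns_report")
}

#' @export
print.ns_report <- function(x, ...) {
  cat(paste(x$markdown, collapse = "\n"), "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain episodes (either generated from a
#' scenario or read from a directory of episode files), segment and
#' summarize suction events, classify HR responses, screen predictors, and
#' write `summaries.json`, `responses.json`, `report.json`, `report.md` and
#' `manifest.json` to `out_dir`. Re-running with the same inputs reproduces
#' identical analysis outputs (the manifest carries a timestamp).
#'
#' @param out_dir Output directory.
#' @param scenario Optional [scenario_config()] to generate a synthetic
#'   cohort (episodes are also serialized under `out_dir/episodes`).
#' @param input_dir Optional directory of episode files (used when
#'   `scenario` is `NULL`).
#' @param config An [analysis_config()].
#' @param run_screen Logical; run [predictor_screen()] (default `TRUE`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, scenario = NULL, input_dir = NULL,
                         config = analysis_config(), run_screen = TRUE) {
  config <- as_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(scenario)) {
    ep_dir <- file.path(out_dir, "episodes")
    coh <- generate_cohort(scenario, out_dir = ep_dir)
    episodes <- coh$episodes
  } else {
    if (is.null(input_dir)) stop("provide either a scenario or an input_dir")
    ids <- list_episode_ids(input_dir)
    if (!length(ids)) stop(sprintf("no episodes found in %s", input_dir))
    episodes <- lapply(ids, function(id) read_episode(input_dir, id))
  }

  bad <- lapply(episodes, validate_episode)
  n_invalid <- sum(vapply(bad, length, integer(1)) > 0)
  if (n_invalid)
    warning(sprintf("%d episode(s) carry validation violations", n_invalid))

  summaries <- do.call(rbind, lapply(episodes, function(ep) {
    ins <- ep$events[ep$events$kind == "suction_insertion", , drop = FALSE]
    ses <- clip_to_window(merge_insertions(ins, config), config)
    summarize_suction(ep, ses, config)
  }))

  classified <- classify_cohort(episodes, config)
  screen <- NULL
  if (run_screen && nrow(classified$responses)) {
    dat <- build_screen_data(classified)
    if (sum(dat$y) >= 5)
      screen <- tryCatch(suppressWarnings(predictor_screen(dat)),
                         error = function(e) NULL)
  }
  report <- make_report(summaries, classified, screen)

  p_sum <- file.path(out_dir, "summaries.json")
  p_resp <- file.path(out_dir, "responses.json")
  p_rep <- file.path(out_dir, "report.json")
  jsonlite::write_json(summaries, p_sum, digits = NA, dataframe = "rows")
  jsonlite::write_json(classified$responses, p_resp, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(report[c("suction", "labels", "mortality")], p_rep,
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  writeLines(report$markdown, file.path(out_dir, "report.md"))

  manifest <- list(
    seed = if (!is.null(scenario)) scenario$seed else NULL,
    n_episodes = length(episodes),
    n_analysed = if (nrow(classified$any_change)) nrow(classified$any_change) else 0L,
    n_excluded = nrow(classified$excluded),
    n_invalid = n_invalid,
    config = unclass(config),
    checksums = as.list(tools::md5sum(c(p_sum, p_resp, p_rep))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
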