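# Fixture builders and independent brute-force oracles used across tests.

flat_hr <- function(duration_s, bpm) {
  t <- seq(1, duration_s)
  data.frame(t_s = t, hr_bpm = rep(bpm, length(t)))
}

suction_ins <- function(start_s, stop_s, site = "mouth", device = "bulb") {
  interval_events(kind = rep("suction_insertion", length(start_s)),
                  start_s = start_s, stop_s = stop_s,
                  site = site, device = device)
}

test_episode <- function(events = interval_events(),
                         hr = flat_hr(300, 140),
                         beats = NULL, duration_s = 300,
                         outcome = "survived") {
  new_episode("t1", outcome, 3100, 38, "male", "clear", 120, TRUE,
              events = events, hr = hr, beats = beats,
              duration_s = duration_s)
}

# Brute-force SE clustering: transitive closure of the pairwise gap
# relation (gap <= max_pause links two insertions), then component spans.
bf_merge_spans <- function(starts, stops, max_pause) {
  n <- length(starts)
  if (!n) return(data.frame(start_s = numeric(), stop_s = numeric()))
  linked <- function(i, j) {
    gap <- max(starts[i], starts[j]) - min(stops[i], stops[j])
    gap <= max_pause
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && linked(i, j)) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  spans <- do.call(rbind, lapply(unique(comp), function(c0) {
    data.frame(start_s = min(starts[comp == c0]), stop_s = max(stops[comp == c0]))
  }))
  spans[order(spans$start_s), , drop = FALSE]
}

# Exact signed-rank null distribution by dynamic-programming convolution
# over rank inclusion (independent of stats::psignrank).
bf_signrank_pmf <- function(n) {
  counts <- c(1, numeric(n * (n + 1) / 2))  # counts[w + 1] = #patterns with W = w
  for (r in seq_len(n)) {
    new <- counts
    idx <- seq_along(counts)[-seq_len(r)]
    new[idx] <- new[idx] + counts[idx - r]
    counts <- new
  }
  counts / 2^n
}

bf_signrank_p_two_sided <- function(x, mu0 = 0) {
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  pmf <- bf_signrank_pmf(n)
  lo <- sum(pmf[seq_len(v + 1)])              # P(W <= v)
  hi <- sum(pmf[(v + 1):length(pmf)])         # P(W >= v)
  min(1, 2 * min(lo, hi))
}

# Hand Pearson chi-square on a 2x2 table.
bf_pearson_2x2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# Brute-force fall scan: any run of >= min_run consecutive samples within
# [start, stop + w] strictly below pre * (1 - frac)? Returns depth of the
# deepest qualifying run (ventilation ignored: oracle for empty vent list).
bf_detect_fall <- function(hr, start, stop, pre, frac, w, min_run) {
  idx <- which(hr$t_s >= start & hr$t_s <= stop + w & !is.na(hr$hr_bpm))
  vals <- hr$hr_bpm[idx]
  thr <- pre * (1 - frac)
  best <- NA_real_
  n <- length(vals)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(vals[i:j] < thr)) {
        if (j - i + 1L >= min_run) {
          depth <- (pre - min(vals[i:j])) / pre
          if (is.na(best) || depth > best) best <- depth
        }
      } else break
    }
  }
  list(flag = !is.na(best), depth = best)
}

# truth/detected comparison on a generated cohort
recovery_rates <- function(cohort, classified) {
  tr <- cohort$truth
  r <- classified$responses
  m <- match(paste(r$newborn_id, r$se_id), paste(tr$newborn_id, tr$se_index))
  tl <- tr$truth_label[m]
  dl <- r$label
  chg_t <- tl %in% c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA")
  chg_d <- dl %in% c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA")
  list(n = nrow(r),
       sensitivity = if (any(chg_t)) sum(chg_t & chg_d) / sum(chg_t) else NA,
       specificity = if (any(!chg_t)) sum(!chg_t & !chg_d) / sum(!chg_t) else NA,
       false_positives = sum(!chg_t & chg_d),
       truth = tl, detected = dl)
}
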