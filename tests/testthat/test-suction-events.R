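cfg <- analysis_config()

test_that("insertions merge by the 5-second pause rule", {
  one <- merge_insertions(suction_ins(c(0, 6), c(3, 9)), cfg)   # gap 3 s
  expect_equal(nrow(one), 1L)
  expect_equal(one$start_s, 0)
  expect_equal(one$stop_s, 9)
  expect_equal(one$n_insertions, 2L)

  two <- merge_insertions(suction_ins(c(0, 9), c(3, 12)), cfg)  # gap 6 s
  expect_equal(nrow(two), 2L)
  expect_equal(two$start_s, c(0, 9))

  # a pause of exactly 5 s does not split (the rule is strictly > 5 s)
  exact <- merge_insertions(suction_ins(c(0, 8), c(3, 10)), cfg)
  expect_equal(nrow(exact), 1L)

  expect_equal(nrow(merge_insertions(suction_ins(numeric(), numeric()), cfg)), 0L)
})

test_that("overlapping insertions collapse to their union with a warning", {
  expect_warning(
    res <- merge_insertions(suction_ins(c(0, 2), c(4, 6)), cfg),
    "overlapping")
  expect_equal(res$n_insertions, 1L)
  expect_equal(res$stop_s, 6)
})

test_that("merging is order-invariant, idempotent, and matches the
           transitive-closure oracle", {
  set.seed(81)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    starts <- round(sort(runif(n, 0, 120)), 2)
    durs <- round(runif(n, 0.5, 6), 2)
    stops <- starts + durs
    # avoid overlaps so no merge warning fires
    for (i in seq_len(n - 1))
      if (stops[i] > starts[i + 1]) stops[i] <- starts[i + 1]
    ins <- suction_ins(starts, stops)

    ses <- merge_insertions(ins, cfg)
    shuf <- merge_insertions(ins[sample(nrow(ins)), ], cfg)
    expect_equal(ses$start_s, shuf$start_s)
    expect_equal(ses$stop_s, shuf$stop_s)

    # idempotent: merging the SE spans changes nothing
    again <- merge_insertions(suction_ins(ses$start_s, ses$stop_s), cfg)
    expect_equal(again$start_s, ses$start_s)
    expect_equal(again$stop_s, ses$stop_s)

    oracle <- bf_merge_spans(starts, stops, cfg$max_pause_s)
    expect_equal(ses$start_s, oracle$start_s)
    expect_equal(ses$stop_s, oracle$stop_s)
  }
})

test_that("events clip to the 420-second analysis window", {
  ses <- merge_insertions(suction_ins(c(400, 430), c(410, 440)), cfg)
  # gap 20 s -> two SEs; second entirely beyond the window
  clipped <- clip_to_window(ses, cfg)
  expect_equal(nrow(clipped), 1L)

  strad <- merge_insertions(suction_ins(c(400, 415), c(412, 440)), cfg)
  expect_equal(nrow(strad), 1L)
  cl <- clip_to_window(strad, cfg)
  expect_equal(cl$stop_s, 420)
  expect_equal(cl$duration_s, 20)

  inf_cfg <- analysis_config(analysis_window_s = Inf)
  expect_equal(clip_to_window(strad, inf_cfg), strad)
})

test_that("suction summaries reproduce counts, durations and proportions", {
  ins <- suction_ins(c(50, 100), c(60, 122))   # SEs of 10 s and 22 s
  ep <- test_episode(events = ins, duration_s = 300)
  ses <- clip_to_window(merge_insertions(ins, cfg), cfg)
  s <- summarize_suction(ep, ses, cfg)
  expect_equal(s$n_se, 2L)
  expect_equal(s$total_suction_s, 32)
  expect_equal(s$proportion_time_suctioning, 32 / 300)
  expect_equal(s$analyzed_window_s, 300)
  expect_true(s$total_suction_s <= s$analyzed_window_s)

  none <- summarize_suction(ep, clip_to_window(merge_insertions(
    suction_ins(numeric(), numeric()), cfg), cfg), cfg)
  expect_equal(none$n_se, 0L)
  expect_equal(none$total_suction_s, 0)
  expect_equal(none$proportion_time_suctioning, 0)

  mix <- suction_ins(c(0, 4, 8, 12), c(2, 6, 10, 14),
                     site = c("mouth", "mouth", "mouth", "nose"))
  ses2 <- merge_insertions(mix, cfg)
  s2 <- summarize_suction(test_episode(events = mix), ses2, cfg)
  expect_equal(s2$insertions_per_se, 4)
  expect_equal(s2$n_mouth, 3L)
  expect_equal(s2$n_nose, 1L)
  expect_equal(s2$n_mouth + s2$n_nose + s2$n_site_unknown, s2$n_insertions)
})

test_that("agreement score is time-in-label-agreement and symmetric", {
  a <- suction_ins(0, 10)
  expect_equal(agreement_score(a, a, 100, cfg)$score, 1)

  b <- suction_ins(0, 8)
  ab <- agreement_score(a, b, 100, cfg)
  expect_equal(ab$score, 0.98)
  expect_false(ab$flagged)
  expect_equal(agreement_score(b, a, 100, cfg)$score, ab$score)

  empty <- interval_events()
  big <- suction_ins(0, 30)
  res <- agreement_score(empty, big, 100, cfg)
  expect_equal(res$score, 0.70)
  expect_true(res$flagged)

  expect_error(agreement_score(a, b, 0, cfg), "positive")
})
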