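cfg <- analysis_config()

se_row <- function(start, stop) {
  data.frame(se_id = 1L, start_s = start, stop_s = stop,
             duration_s = stop - start, n_insertions = 1L, n_mouth = 1L,
             n_nose = 0L, n_site_unknown = 0L, any_catheter = FALSE,
             any_bulb = TRUE, devices = "bulb")
}

test_that("pre/post heart rate is the median of the five nearest samples", {
  hr <- data.frame(t_s = c(85:89, 101:105),
                   hr_bpm = c(150, 148, 152, 151, 149, 130, 131, 132, 133, 134))
  se <- se_row(90, 100)
  pp <- pre_post_hr(hr, se, cfg)
  expect_equal(pp[["pre"]], 150)
  expect_equal(pp[["post"]], 132)

  # seven samples in the pre window: the five nearest the boundary are used
  hr7 <- data.frame(t_s = 83:89, hr_bpm = c(999, 999, 150, 148, 152, 151, 149))
  expect_equal(pre_post_hr(hr7, se, cfg)[["pre"]], 150)

  # two samples (< min_hr_samples = 3) -> missing
  hr2 <- data.frame(t_s = c(88, 89), hr_bpm = c(150, 151))
  expect_true(is.na(pre_post_hr(hr2, se, cfg)[["pre"]]))

  # exactly four samples (>= 3, < 5): median of those four
  hr4 <- data.frame(t_s = 86:89, hr_bpm = c(150, 148, 152, 154))
  expect_equal(pre_post_hr(hr4, se, cfg)[["pre"]], 151)
})

test_that("falls require >15% below pre-SE HR, persistence, and no
           concurrent ventilation", {
  base <- flat_hr(200, 150)
  se <- se_row(100, 110)
  no_vent <- interval_events()

  dip <- base
  dip$hr_bpm[dip$t_s %in% 103:106] <- 120      # 20% fall for 4 s
  res <- detect_fall(dip, se, 150, no_vent, cfg)
  expect_true(res$flag)
  expect_equal(res$max_fall_fraction, 0.20)

  shallow <- base
  shallow$hr_bpm[shallow$t_s %in% 103:106] <- 128   # 14.7%: below the bar
  expect_false(detect_fall(shallow, se, 150, no_vent, cfg)$flag)

  deep_vented <- base
  deep_vented$hr_bpm[deep_vented$t_s %in% 103:106] <- 110
  vent <- interval_events("ventilation", 102, 108)
  expect_false(detect_fall(deep_vented, se, 150, vent, cfg)$flag)

  # a single sub-threshold sample is not a fall
  blip <- base
  blip$hr_bpm[blip$t_s == 104] <- 110
  expect_false(detect_fall(blip, se, 150, no_vent, cfg)$flag)
})

test_that("fall detection matches a brute-force window scan", {
  set.seed(512)
  se <- se_row(20, 30)
  for (rep in 1:40) {
    hr <- data.frame(t_s = 1:50, hr_bpm = round(runif(50, 100, 160)))
    pre <- 150
    mine <- detect_fall(hr, se, pre, interval_events(), cfg)
    oracle <- bf_detect_fall(hr, 20, 30, pre, cfg$fall_fraction,
                             cfg$hr_window_s, cfg$fall_min_samples)
    expect_identical(mine$flag, oracle$flag)
    if (oracle$flag) expect_equal(mine$max_fall_fraction, oracle$depth)
  }
})

test_that("bigeminy needs 8 alternating beats at RR ratio >= 1.5", {
  big <- cumsum(c(10, rep(c(0.3, 0.6), 5)))
  expect_true(detect_bigeminy(big, c(10, 20)))

  steady <- seq(10, 20, by = 0.45)
  expect_false(detect_bigeminy(steady, c(10, 20)))

  weak <- cumsum(c(10, rep(c(0.40, 0.50), 6)))   # ratio 1.25
  expect_false(detect_bigeminy(weak, c(10, 20)))

  expect_false(detect_bigeminy(big[1:6], c(10, 20)))  # too few beats
  expect_false(detect_bigeminy(NULL, c(10, 20)))
})

test_that("classification follows the precedence rules", {
  se <- se_row(100, 110)

  # PPV ceased 2 s before the SE and HR fell 38 bpm: unrelated to suction
  hr <- flat_hr(200, 150)
  hr$hr_bpm[hr$t_s %in% 105:112] <- 112
  ep <- test_episode(events = rbind(
    interval_events("ventilation", 80, 98),
    suction_ins(100, 110)), hr = hr)
  expect_equal(classify_se(ep, se, cfg)$label, "VENT_CESSATION_FALL")

  # same fall with no recent ventilation: suction-related
  ep2 <- test_episode(events = suction_ins(100, 110), hr = hr)
  r2 <- classify_se(ep2, se, cfg)
  expect_equal(r2$label, "SUCTION_RELATED_FALL")
  expect_false(r2$concurrent_ventilation)

  # ventilation ceased long before (gap > 5 s) does not reroute the label
  ep3 <- test_episode(events = rbind(
    interval_events("ventilation", 60, 85),
    suction_ins(100, 110)), hr = hr)
  r3 <- classify_se(ep3, se, cfg)
  expect_equal(r3$label, "SUCTION_RELATED_FALL")
  expect_true(r3$ventilation_prior)

  # flat heart rate: no change, delta ~ 0
  flat_ep <- test_episode(events = suction_ins(100, 110))
  rf <- classify_se(flat_ep, se, cfg)
  expect_equal(rf$label, "NO_CHANGE")
  expect_equal(rf$delta_hr_bpm, 0)

  # bigeminy overlapping the SE dominates a shallow profile
  beats <- cumsum(c(100, rep(c(0.3, 0.6), 10)))
  arr_ep <- test_episode(events = suction_ins(100, 110), beats = beats)
  expect_equal(classify_se(arr_ep, se, cfg)$label, "SUCTION_RELATED_ARRHYTHMIA")

  # missing HR coverage and no arrhythmia: indeterminate
  sparse <- test_episode(events = suction_ins(100, 110),
                         hr = data.frame(t_s = c(95, 96), hr_bpm = c(150, 150)))
  expect_equal(classify_se(sparse, se, cfg)$label, "INDETERMINATE")
})

test_that("labels are mutually exclusive and exhaustive over a cohort", {
  coh <- generate_cohort(scenario_config(40, seed = 4))
  cl <- classify_cohort(coh$episodes)
  labs <- cl$responses$label
  expect_true(all(labs %in% c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA",
                              "VENT_CESSATION_FALL", "NO_CHANGE", "INDETERMINATE")))
  expect_false(any(is.na(labs)))
})

test_that("raising the fall threshold never increases fall labels", {
  coh <- generate_cohort(scenario_config(40, seed = 6))
  counts <- vapply(c(0.10, 0.15, 0.20, 0.30), function(f) {
    cl <- classify_cohort(coh$episodes, analysis_config(fall_fraction = f))
    sum(cl$responses$label == "SUCTION_RELATED_FALL")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("episodes without usable HR coverage are excluded and logged", {
  good <- generate_cohort(scenario_config(3, seed = 12))$episodes
  bad <- test_episode(events = suction_ins(c(50, 60), c(55, 65)),
                      hr = data.frame(t_s = numeric(), hr_bpm = numeric()))
  bad$newborn_id <- "empty_hr"
  cl <- classify_cohort(c(good, list(bad)))
  expect_true("empty_hr" %in% cl$excluded$newborn_id)
  expect_false("empty_hr" %in% cl$responses$newborn_id)
  expect_match(cl$excluded$reason[cl$excluded$newborn_id == "empty_hr"],
               "indeterminate")
})
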