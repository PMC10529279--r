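test_that("generation is deterministic and cohort-size invariant", {
  sc <- scenario_config(3, seed = 42)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  # the same newborn is reproduced regardless of cohort size
  big <- generate_cohort(scenario_config(8, seed = 42))
  expect_identical(serialize(a$episodes[[2]], NULL),
                   serialize(big$episodes[[2]], NULL))
})

test_that("zero change probabilities yield only NO_CHANGE truths", {
  sc <- scenario_config(25, seed = 9, p_suction_related_change = 0,
                        p_vent_cessation_change = 0)
  tr <- generate_cohort(sc)$truth
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$truth_label == "NO_CHANGE"))
})

test_that("planted falls reach their nominal depth in the noiseless signal", {
  sc <- scenario_config(40, seed = 21, hr_noise_sd_bpm = 0, p_missing_hr = 0)
  coh <- generate_cohort(sc)
  checked <- 0L
  for (i in seq_along(coh$episodes)) {
    ep <- coh$episodes[[i]]
    tr <- coh$truth[coh$truth$newborn_id == ep$newborn_id &
                      coh$truth$truth_label == "SUCTION_RELATED_FALL", ,
                    drop = FALSE]
    if (!nrow(tr)) next
    clean <- attr(ep, "hr_noisefree")
    for (j in seq_len(nrow(tr))) {
      pre <- clean$hr_bpm[max(which(clean$t_s < tr$se_start_s[j]))]
      win <- clean$hr_bpm[clean$t_s >= tr$se_start_s[j] &
                            clean$t_s <= tr$se_stop_s[j] + 20]
      expect_gte((pre - min(win)) / pre, 0.20)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("every generated episode is well formed", {
  coh <- generate_cohort(scenario_config(30, seed = 3))
  for (ep in coh$episodes) expect_identical(validate_episode(ep), character(0))
  expect_equal(length(coh$episodes), 30L)

  single <- generate_cohort(scenario_config(1, seed = 8))
  expect_length(single$episodes, 1L)
  expect_identical(validate_episode(single$episodes[[1]]), character(0))
})

test_that("planted rates are calibrated to their configured probabilities", {
  sc <- scenario_config(500, seed = 2)
  coh <- generate_cohort(sc)
  tr <- coh$truth
  n_se <- nrow(tr)
  chg <- tr$truth_label %in% c("SUCTION_RELATED_FALL", "SUCTION_RELATED_ARRHYTHMIA")

  # exact binomial 99% interval around the configured per-SE change rate
  ci <- qbinom(c(0.005, 0.995), n_se, sc$p_suction_related_change) / n_se
  expect_gte(mean(chg), ci[1])
  expect_lte(mean(chg), ci[2])

  died <- vapply(coh$episodes, function(e) e$outcome == "died_3d", logical(1))
  names(died) <- vapply(coh$episodes, function(e) e$newborn_id, character(1))
  baby_chg <- tapply(chg, tr$newborn_id, any)
  d_chg <- died[names(baby_chg)][baby_chg]
  d_no <- died[names(baby_chg)][!baby_chg]
  ci_c <- qbinom(c(0.005, 0.995), length(d_chg), sc$p_death_given_change) / length(d_chg)
  ci_n <- qbinom(c(0.005, 0.995), length(d_no), sc$p_death_given_no_change) / length(d_no)
  expect_gte(mean(d_chg), ci_c[1]); expect_lte(mean(d_chg), ci_c[2])
  expect_gte(mean(d_no), ci_n[1]); expect_lte(mean(d_no), ci_n[2])
})

test_that("the second annotator perturbs the timeline as requested", {
  g <- generate_episode(scenario_config(1, seed = 1), 77, "nbA")
  ep <- g$episode
  expect_gt(nrow(ep$events), 0)

  same <- generate_second_annotator(ep, jitter_sd_s = 0, p_miss = 0, seed = 5)
  expect_equal(same, ep$events)

  one_left <- generate_second_annotator(ep, jitter_sd_s = 0, p_miss = 1, seed = 5)
  expect_gte(nrow(one_left), 1L)

  jit <- generate_second_annotator(ep, jitter_sd_s = 1, p_miss = 0, seed = 5)
  sc2 <- agreement_score(ep$events, jit, ep$duration_s)$score
  expect_gt(sc2, 0)
  expect_lt(sc2, 1)
})

test_that("degenerate scenarios are rejected", {
  expect_error(scenario_config(10, episode_duration_min = 5,
                               episode_duration_max = 20), "degenerate")
  expect_error(scenario_config(0), "n_newborns")
  expect_error(scenario_config(10, p_suctioned = 1.4), "\\[0, 1\\]")
})
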