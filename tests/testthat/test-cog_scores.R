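rt_trials <- function(rts, correct = TRUE) {
  data.frame(rt_ms = rts, correct = correct)
}

test_that("reaction-time scoring and minima", {
  tr <- rt_trials(rep(c(300, 320, 340), 5))
  s <- score_reaction_time(tr, "srt")
  expect_equal(s$score, 320)
  expect_true(s$valid)
  # 11 trials: score computed but invalid
  s11 <- score_reaction_time(rt_trials(rep(300, 11)), "srt")
  expect_equal(s11$score, 300)
  expect_false(s11$valid)
  # crt needs 24
  s24 <- score_reaction_time(rt_trials(rep(c(400, 500), 12)), "crt")
  expect_equal(s24$score, 450)
  expect_true(s24$valid)
  expect_false(score_reaction_time(rt_trials(rep(400, 23)), "crt")$valid)
  # too-slow responses are executed but not correct
  slow <- rt_trials(c(rep(300, 12), 3500), correct = c(rep(TRUE, 12), TRUE))
  s <- score_reaction_time(slow, "srt")
  expect_equal(s$score, 300)
  expect_equal(s$n_executed, 12L)
  # medians invariant to order and duplication
  shuf <- rt_trials(sample(rep(c(300, 320, 340), 5)))
  expect_equal(score_reaction_time(shuf, "srt")$score, 320)
  expect_equal(score_reaction_time(rbind(tr, tr), "srt")$score, 320)
})

test_that("task-switch global and local costs", {
  mk <- function(pure, mixed_ns, mixed_sw) {
    rbind(data.frame(rt_ms = pure, correct = TRUE,
                     block_type = rep(c("pure_shape", "pure_color"),
                                      length.out = length(pure)),
                     is_switch_trial = NA),
          data.frame(rt_ms = mixed_ns, correct = TRUE,
                     block_type = "mixed", is_switch_trial = FALSE),
          data.frame(rt_ms = mixed_sw, correct = TRUE,
                     block_type = "mixed", is_switch_trial = TRUE))
  }
  tr <- mk(rep(500, 10), rep(600, 10), rep(700, 10))
  s <- score_task_switch(tr)
  expect_equal(s$global_cost, (650 - 500) / 500, tolerance = 1e-12)
  expect_equal(s$local_cost, (700 - 600) / 600, tolerance = 1e-12)
  expect_true(s$valid)
  # equal medians -> zero global cost
  s0 <- score_task_switch(mk(rep(600, 10), rep(600, 10), rep(600, 10)))
  expect_equal(s0$global_cost, 0)
  # missing pure blocks -> invalid
  tr2 <- tr[tr$block_type == "mixed", ]
  expect_false(score_task_switch(tr2)$valid)
  # fewer than 12 executed trials -> invalid
  expect_false(score_task_switch(mk(rep(500, 4), rep(600, 3),
                                    rep(700, 3)))$valid)
})

test_that("Corsi termination rule", {
  mk <- function(lens, correct) {
    data.frame(sequence_length = lens, correct = correct)
  }
  # correct at 2..6, two consecutive errors at 7 -> span 6
  tr <- mk(c(2, 3, 4, 5, 6, 7, 7), c(rep(TRUE, 5), FALSE, FALSE))
  expect_equal(score_corsi(tr)$span, 6L)
  # all nine correct -> span 9
  expect_equal(score_corsi(mk(2:9, TRUE))$span, 9L)
  # two errors at the start -> span 0
  s0 <- score_corsi(mk(c(2, 2), c(FALSE, FALSE)))
  expect_equal(s0$span, 0L)
  expect_true(s0$valid)   # two trials meet the minimum
  expect_false(score_corsi(mk(2, TRUE))$valid)
  # a single error recovers; trials after the double error are ignored
  tr2 <- mk(c(2, 3, 3, 4, 5, 5, 9), c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                      TRUE, TRUE))
  expect_equal(score_corsi(tr2)$span, 3L)
})

test_that("2-back d-prime with clipping", {
  mk <- function(n_t, n_nt, hits, fas) {
    data.frame(is_target = c(rep(TRUE, n_t), rep(FALSE, n_nt)),
               responded = c(rep(TRUE, hits), rep(FALSE, n_t - hits),
                             rep(TRUE, fas), rep(FALSE, n_nt - fas)))
  }
  # hit 0.9, fa 0.1 -> 2.5631 (inverse-normal oracle)
  s <- score_nback(mk(30, 60, 27, 6))
  expect_equal(s$dprime, qnorm(0.9) - qnorm(0.1), tolerance = 1e-12)
  expect_equal(round(s$dprime, 4), 2.5631)
  expect_true(s$valid)
  # hit == fa -> 0
  expect_equal(score_nback(mk(30, 30, 15, 15))$dprime, 0)
  # perfect hits clipped to 1 - 1/(2*30)
  sp <- score_nback(mk(30, 60, 30, 6))
  expect_equal(sp$hit_rate, 1 - 1 / 60)
  expect_true(is.finite(sp$dprime))
  # antisymmetry under swapping hit and false-alarm rates
  a <- score_nback(mk(30, 30, 24, 9))$dprime
  b <- score_nback(mk(30, 30, 9, 24))$dprime
  expect_equal(a, -b, tolerance = 1e-12)
  # monotone in hit rate
  expect_lt(score_nback(mk(30, 60, 20, 6))$dprime,
            score_nback(mk(30, 60, 25, 6))$dprime)
  expect_false(score_nback(mk(10, 19, 9, 2))$valid)  # 29 trials
  expect_false(score_nback(mk(0, 30, 0, 3))$valid)
})

test_that("finger preference scales", {
  ranks <- setNames(1:8, finger_postures)  # left_thumb ranked 1
  s <- finger_scales(ranks)
  expect_equal(s$thumb_pref, 1)
  expect_equal(s$dual_thumb_pref, (8 - 3) / 7)
  # best thumb image ranked 8 -> 0
  worst <- setNames(c(8, 7, 6, 5, 1, 2, 3, 4), finger_postures)
  expect_equal(finger_scales(worst)$thumb_pref, (8 - 5) / 7)
  # dual portrait 4, landscape 6 -> 4/7
  r <- setNames(c(1, 2, 4, 6, 3, 5, 7, 8), finger_postures)
  expect_equal(finger_scales(r)$dual_thumb_pref, (8 - 4) / 7)
  expect_equal(round(finger_scales(r)$dual_thumb_pref, 4), 0.5714)
  # promotion of a relevant image never decreases the scale
  r2 <- r; r2[["both_thumbs_portrait"]] <- 2; r2[["right_thumb"]] <- 4
  expect_gte(finger_scales(r2)$dual_thumb_pref,
             finger_scales(r)$dual_thumb_pref)
  expect_error(finger_scales(setNames(rep(1, 8), finger_postures)),
               "permutation")
})

test_that("participant-level scoring table carries validity flags", {
  co <- local_small_cohort()
  sc <- score_participants(co$trials)
  expect_equal(nrow(sc), 25L)
  expect_true(all(c("srt_median_ms", "crt_median_ms", "global_cost",
                    "corsi_span", "nback_dprime") %in% names(sc)))
  expect_true(all(sc$corsi_span >= 0 & sc$corsi_span <= 9))
  # generated trials meet the minima, so flags are true
  expect_true(all(sc$srt_valid))
  expect_true(all(sc$nback_valid))
})
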