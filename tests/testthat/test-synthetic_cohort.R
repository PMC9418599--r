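test_that("generation is deterministic and structurally valid", {
  spec <- cohort_spec(n_participants = 6, seed = 99, days = 3,
                      sessions_per_day = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$events, b$events)
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)
  expect_equal(nrow(a$participants), 6L)
  expect_true(all(a$participants$age_years >= 16 &
                    a$participants$age_years <= 86))
  expect_true(all(a$participants$gender %in% 1:2))
  # events strictly inside their episodes, timestamps unique
  s <- segment_sessions(a$events, a$episodes)
  expect_equal(attr(s, "n_dropped"), 0L)
  expect_true(all(a$episodes$off_ms > a$episodes$on_ms))
  # different seed gives different data
  c2 <- generate_cohort(cohort_spec(n_participants = 6, seed = 100,
                                    days = 3, sessions_per_day = 5))
  expect_false(identical(a$events$timestamp_ms, c2$events$timestamp_ms))
  expect_error(cohort_spec(n_participants = 0), "participant")
})

test_that("ITI mixture marginals track the age-dependent fast weight", {
  spec <- cohort_spec(n_participants = 12, seed = 41, days = 6,
                      sessions_per_day = 12, pace_loading = 0)
  co <- generate_cohort(spec)
  s <- segment_sessions(co$events, co$episodes)
  pids <- vapply(s, `[[`, character(1), "participant_id")
  for (i in c(1, 6, 12)) {
    pid <- co$participants$participant_id[i]
    age <- co$participants$age_years[i]
    itis <- unlist(lapply(s[pids == pid],
                          function(x) extract_itis(x)$iti_ms))
    # classify by the mixture crossover (log10 midpoint 2.8)
    p_fast <- mean(log10(itis) < 2.8)
    w <- tapjid:::fast_weight(spec, age)
    expect_lt(abs(p_fast - w), 3 * sqrt(w * (1 - w) / length(itis)) + 0.02)
  }
  # older participants have stochastically longer intervals
  ages <- co$participants$age_years
  young <- co$participants$participant_id[which.min(ages)]
  old <- co$participants$participant_id[which.max(ages)]
  iti_y <- unlist(lapply(s[pids == young],
                         function(x) extract_itis(x)$iti_ms))
  iti_o <- unlist(lapply(s[pids == old],
                         function(x) extract_itis(x)$iti_ms))
  ks <- suppressWarnings(ks.test(iti_y, iti_o, alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})

test_that("planted truth matches numeric differentiation of the mixture", {
  spec <- cohort_spec()
  tr <- planted_truth(spec)
  expect_true(all(tr$age_sign[tr$fast_region] == -1))
  expect_true(all(tr$age_sign[tr$slow_region] == 1))
  # independent coarse check of the sign field: finite differences of
  # the expected (KDE-smoothed) mixture grid at two ages
  cfg <- jid_config()
  b <- jid_bins(cfg)
  marg <- function(age) {
    w <- min(max(spec$fast_weight_base -
                   spec$fast_weight_age_slope * (age - 16), 0.05), 0.95)
    sds <- sqrt(spec$iti_sds_log10^2 + cfg$bandwidth^2)
    w * dnorm(b$centers, spec$iti_means_log10[1], sds[1]) +
      (1 - w) * dnorm(b$centers, spec$iti_means_log10[2], sds[2])
  }
  g <- function(age) { m <- outer(marg(age), marg(age)); m / sum(m) }
  d <- g(60) - g(40)
  coarse <- seq(3, 48, by = 5)
  for (i in coarse) for (j in coarse) {
    if (abs(d[i, j]) > 1e-6) {
      expect_equal(sign(d[i, j]), tr$age_sign[i, j])
    }
  }
  # pace loadings: positive pace -> more fast mass
  expect_true(all(tr$pace_sign[tr$fast_region] == 1))
  # expected pair labels follow the triple product
  fast_bin <- c(17, 17); slow_bin <- c(35, 35)
  expect_equal(expected_pair_label(tr, fast_bin, slow_bin),
               ifelse(tr$pace_sign[17, 17] * tr$pace_sign[35, 35] *
                        tr$age_sign[17, 17] * tr$age_sign[35, 35] > 0,
                      "consistent", "inconsistent"))
})

test_that("cohort artifacts write to plain-text files", {
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 8,
                                    days = 2, sessions_per_day = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("events.csv", "episodes.csv", "participants.csv",
           "trials.csv", "truth.json")))))
  back <- load_events(file.path(dir, "events.csv"))
  expect_equal(back$timestamp_ms, co$events$timestamp_ms)
  expect_equal(back$app_id, co$events$app_id)
})

test_that("worked example stream has the documented shape", {
  w <- worked_example_stream()
  expect_equal(nrow(w$events), 6L)
  s <- segment_sessions(w$events, w$episodes)
  expect_length(s, 1L)
  itis <- extract_itis(s[[1]])
  expect_equal(nrow(itis), 5L)
  expect_equal(nrow(select_pairs(itis, jid_config())), 4L)
  j <- compute_jid(select_pairs(itis, jid_config()), jid_config())
  expect_equal(sum(j$masses), 1, tolerance = 1e-9)
})
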