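test_that("event CSV round trip, malformed rows and missing columns", {
  ev <- data.frame(participant_id = c("p1", "p1", "p2"),
                   timestamp_ms = c(10, 20, 30),
                   app_id = c("a", "b", "a"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- load_events(path)
  expect_equal(back$participant_id, ev$participant_id)
  expect_equal(back$timestamp_ms, ev$timestamp_ms)
  expect_equal(back$app_id, ev$app_id)

  # header-only file: empty table, no error
  writeLines("participant_id,timestamp_ms,app_id", path)
  expect_equal(nrow(load_events(path)), 0L)

  # missing app_id column names the column
  writeLines(c("participant_id,timestamp_ms", "p1,10"), path)
  expect_error(load_events(path), "app_id")

  # non-numeric timestamp dropped with line number in the warning
  writeLines(c("participant_id,timestamp_ms,app_id",
               "p1,10,a", "p1,oops,b", "p1,30,c"), path)
  expect_warning(res <- load_events(path), "line")
  expect_equal(nrow(res), 2L)
  expect_equal(attr(res, "n_malformed"), 1L)

  # duplicate timestamps collapsed
  writeLines(c("participant_id,timestamp_ms,app_id",
               "p1,0,a", "p1,0,a", "p1,50,b"), path)
  res <- load_events(path)
  expect_equal(res$timestamp_ms, c(0, 50))
  expect_equal(attr(res, "n_duplicates"), 1L)
})

test_that("session segmentation assigns, drops and merges correctly", {
  ev <- data.frame(participant_id = "p",
                   timestamp_ms = c(0, 100, 200, 600),
                   app_id = "a")
  ep <- data.frame(participant_id = "p", on_ms = -10, off_ms = 500)
  s <- segment_sessions(ev, ep)
  expect_length(s, 1L)
  expect_equal(s[[1]]$timestamps, c(0, 100, 200))
  expect_equal(attr(s, "n_dropped"), 1L)

  # two episodes -> two sessions, never a cross-session interval
  f <- fixture_two_participants()
  s <- segment_sessions(f$events, f$episodes)
  expect_length(s, 4L)
  counts <- vapply(s, function(x) length(x$timestamps), integer(1))
  expect_equal(sum(counts) + attr(s, "n_dropped"), nrow(f$events))
  # boundary touch at off_ms belongs to the episode (closed interval)
  ev2 <- data.frame(participant_id = "p", timestamp_ms = c(0, 500),
                    app_id = "a")
  s2 <- segment_sessions(ev2, ep)
  expect_equal(s2[[1]]$timestamps, c(0, 500))

  # overlapping episodes merged with a warning
  ep3 <- data.frame(participant_id = "p", on_ms = c(0, 300),
                    off_ms = c(400, 800))
  expect_warning(s3 <- segment_sessions(ev, ep3), "merged")
  expect_length(s3, 1L)
  expect_equal(s3[[1]]$timestamps, c(0, 100, 200, 600))
})

test_that("interval extraction conserves time and labels apps", {
  ses <- list(participant_id = "p", timestamps = c(0, 100, 350),
              app_ids = c("a", "b", "b"), on_ms = -1, off_ms = 400)
  itis <- extract_itis(ses)
  expect_equal(itis$iti_ms, c(100, 250))
  expect_equal(itis$lead_app, c("a", "b"))
  expect_equal(itis$trail_app, c("b", "b"))
  expect_equal(sum(itis$iti_ms), 350 - 0)

  # single touch -> empty, not an error
  one <- list(participant_id = "p", timestamps = 5, app_ids = "a",
              on_ms = 0, off_ms = 10)
  expect_equal(nrow(extract_itis(one)), 0L)

  # six touches -> five intervals, four consecutive pairs
  w <- worked_example_stream()
  s <- segment_sessions(w$events, w$episodes)
  expect_length(s, 1L)
  itis <- extract_itis(s[[1]])
  expect_equal(nrow(itis), 5L)
  expect_equal(nrow(select_pairs(itis, jid_config())), 4L)
})

test_that("cohort filter applies the 7-day / 100-touch rule", {
  day <- 86400000
  mk <- function(id, days, n) {
    data.frame(participant_id = id,
               timestamp_ms = seq(0, days * day, length.out = n),
               app_id = "a")
  }
  ev <- rbind(mk("keep", 10, 5000), mk("short", 6, 5000),
              mk("sparse", 30, 99))
  out <- filter_cohort(ev)
  expect_equal(unique(out$participant_id), "keep")
  audit <- attr(out, "audit")
  expect_equal(audit$retained[audit$participant_id == "short"], FALSE)
  expect_equal(audit$retained[audit$participant_id == "sparse"], FALSE)
  # exactly 7 days span and 100 touches is retained (>=)
  ev2 <- mk("edge", 7, 100)
  expect_equal(nrow(filter_cohort(ev2)), 100L)
})

test_that("test-day windowing keeps +/-10 days inclusive and flags empties", {
  day <- 86400000
  offs <- c(-12, -3, 0, 4, 11)
  ev <- data.frame(participant_id = "p",
                   timestamp_ms = 100 * day + offs * day,
                   app_id = "a")
  out <- window_around_test(ev, 100 * day)
  expect_equal((out$timestamp_ms - 100 * day) / day, c(-3, 0, 4))
  # all inside -> identity
  out2 <- window_around_test(ev[2:4, ], 100 * day)
  expect_equal(nrow(out2), 3L)
  # none inside -> flagged
  out3 <- window_around_test(ev[1, , drop = FALSE], 100 * day)
  expect_equal(nrow(out3), 0L)
  expect_equal(attr(out3, "excluded"), "p")
  # boundary day is inclusive
  out4 <- window_around_test(
    data.frame(participant_id = "p", timestamp_ms = 110 * day,
               app_id = "a"), 100 * day)
  expect_equal(nrow(out4), 1L)
})
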