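#' Read a touch-event log
#'
#' Events are stored as CSV with header
#' `participant_id,timestamp_ms,app_id`, one row per touchscreen touch.
#' Timestamps are integer epoch milliseconds. Rows with a non-numeric or
#' negative timestamp are dropped with a warning naming the offending
#' lines; duplicate timestamps within a participant (simultaneous
#' multi-finger touches) are collapsed to a single event because a
#' zero-length interval is undefined on the log scale.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `participant_id`, `timestamp_ms`
#'   (double ms), `app_id`, sorted by participant then timestamp. The
#'   number of dropped malformed rows is attached as attribute
#'   `n_malformed`, collapsed duplicates as `n_duplicates`.
#' @export
load_events <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("participant_id", "timestamp_ms", "app_id")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("event file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(raw$timestamp_ms))
  bad <- is.na(ts) | ts < 0
  if (any(bad)) {
    # +1 for the header line so the numbers match the file
    warning(sprintf("dropping %d malformed event row(s) at line(s) %s",
                    sum(bad),
                    paste(head(which(bad) + 1L, 20L), collapse = ", ")),
            call. = FALSE)
  }
  ev <- data.frame(participant_id = raw$participant_id[!bad],
                   timestamp_ms = ts[!bad],
                   app_id = raw$app_id[!bad],
                   stringsAsFactors = FALSE)
  ev <- sort_events(ev)
  n0 <- nrow(ev)
  ev <- collapse_duplicate_touches(ev)
  attr(ev, "n_malformed") <- sum(bad)
  attr(ev, "n_duplicates") <- n0 - nrow(ev)
  ev
}

#' Write a touch-event log
#'
#' Inverse of [load_events()]: writes the standard three-column CSV so
#' that a write/read round trip is the identity on
#' (`participant_id`, `timestamp_ms`, `app_id`).
#'
#' @param events Event table as returned by [load_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("participant_id", "timestamp_ms", "app_id") %in%
                  names(events)))
  out <- data.frame(participant_id = events$participant_id,
                    timestamp_ms = format(events$timestamp_ms,
                                          scientific = FALSE, trim = TRUE),
                    app_id = events$app_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screen-episode log
#'
#' CSV with header `participant_id,on_ms,off_ms`; one row per screen
#' on/off episode.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with `participant_id`, `on_ms`, `off_ms`.
#' @export
load_episodes <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "on_ms", "off_ms")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("episode file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(raw$off_ms <= raw$on_ms)) {
    stop("episodes must satisfy off_ms > on_ms", call. = FALSE)
  }
  raw[order(raw$participant_id, raw$on_ms), required]
}

#' Read a participant metadata table
#'
#' CSV with header `participant_id,age_years,gender,thumb_pref,
#' dual_thumb_pref,years_smartphone,screen_size_inch`; the last four
#' columns may be empty. Gender is coded numerically, 1 = male,
#' 2 = female.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` of participant metadata.
#' @export
load_participants <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "age_years", "gender")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("participant file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw
}

sort_events <- function(events) {
  events[order(events$participant_id, events$timestamp_ms), , drop = FALSE]
}

collapse_duplicate_touches <- function(events) {
  dup <- duplicated(events[c("participant_id", "timestamp_ms")])
  out <- events[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge overlapping (or touching) episodes per participant so every
# timestamp belongs to at most one episode.
normalize_episodes <- function(episodes) {
  merged_any <- FALSE
  out <- lapply(split(episodes, episodes$participant_id), function(ep) {
    ep <- ep[order(ep$on_ms), , drop = FALSE]
    if (nrow(ep) <= 1L) return(ep)
    on <- ep$on_ms[1]; off <- ep$off_ms[1]
    res_on <- numeric(0); res_off <- numeric(0)
    for (i in seq_len(nrow(ep))[-1]) {
      if (ep$on_ms[i] <= off) {   # overlap or shared boundary: merge
        merged_any <<- TRUE
        off <- max(off, ep$off_ms[i])
      } else {
        res_on <- c(res_on, on); res_off <- c(res_off, off)
        on <- ep$on_ms[i]; off <- ep$off_ms[i]
      }
    }
    res_on <- c(res_on, on); res_off <- c(res_off, off)
    data.frame(participant_id = ep$participant_id[1],
               on_ms = res_on, off_ms = res_off,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (merged_any) {
    warning("overlapping screen episodes were merged", call. = FALSE)
  }
  out
}

#' Segment touch events into usage sessions
#'
#' A usage session is the period from the screen turning on to being
#' switched off; inter-touch intervals never span sessions. Each touch is
#' assigned to the episode whose closed interval `[on_ms, off_ms]`
#' contains it (boundaries inclusive); touches outside every episode are
#' dropped and counted. Overlapping episodes are merged with a warning.
#'
#' @param events Event table (see [load_events()]).
#' @param episodes Episode table (see [load_episodes()]).
#' @return A list of sessions, each a list with `participant_id`,
#'   `timestamps`, `app_ids`, `on_ms`, `off_ms`. Episodes that contain no
#'   touch produce no session. Attribute `n_dropped` counts touches that
#'   fell outside all episodes.
#' @export
segment_sessions <- function(events, episodes) {
  events <- collapse_duplicate_touches(sort_events(events))
  episodes <- normalize_episodes(episodes)
  ev_split <- split(events, events$participant_id)
  sessions <- list()
  dropped <- 0L
  for (pid in names(ev_split)) {
    ev <- ev_split[[pid]]
    ep <- episodes[episodes$participant_id == pid, , drop = FALSE]
    if (nrow(ep) == 0L) {
      dropped <- dropped + nrow(ev)
      next
    }
    # episodes are disjoint and sorted; locate each touch
    idx <- findInterval(ev$timestamp_ms, ep$on_ms)
    inside <- idx >= 1L & ev$timestamp_ms <= ep$off_ms[pmax(idx, 1L)]
    dropped <- dropped + sum(!inside)
    ev <- ev[inside, , drop = FALSE]
    idx <- idx[inside]
    for (j in unique(idx)) {
      sel <- idx == j
      sessions[[length(sessions) + 1L]] <- list(
        participant_id = pid,
        timestamps = ev$timestamp_ms[sel],
        app_ids = ev$app_id[sel],
        on_ms = ep$on_ms[j],
        off_ms = ep$off_ms[j])
    }
  }
  attr(sessions, "n_dropped") <- dropped
  class(sessions) <- c("tap_sessions", "list")
  sessions
}

#' Extract inter-touch intervals from a session
#'
#' `n` touches yield `n - 1` strictly positive intervals; interval `i`
#' carries the app of its leading touch (`i`) and trailing touch
#' (`i + 1`). A single-touch session yields zero intervals, which is not
#' an error.
#'
#' @param session One element of the list returned by
#'   [segment_sessions()].
#' @return `data.frame` with columns `iti_ms`, `lead_app`, `trail_app`
#'   and attribute `participant_id`.
#' @export
extract_itis <- function(session) {
  ts <- session$timestamps
  stopifnot(length(ts) >= 1L)
  if (is.unsorted(ts, strictly = TRUE)) {
    ts_u <- sort(unique(ts))
    keep <- match(ts_u, ts)
    session$app_ids <- session$app_ids[keep]
    ts <- ts_u
  }
  n <- length(ts)
  out <- data.frame(
    iti_ms = if (n > 1L) diff(ts) else numeric(0),
    lead_app = if (n > 1L) session$app_ids[-n] else character(0),
    trail_app = if (n > 1L) session$app_ids[-1L] else character(0),
    stringsAsFactors = FALSE)
  attr(out, "participant_id") <- session$participant_id
  out
}

#' Apply the cohort inclusion filter
#'
#' Participants are retained when their recording span (last minus first
#' event timestamp) is at least `min_days` days and they contributed at
#' least `min_touches` touches in that period.
#'
#' @param events Event table.
#' @param min_days Minimum recording span in days (default 7).
#' @param min_touches Minimum number of touches (default 100).
#' @return Filtered event table; the per-participant audit (span, count,
#'   retained flag) is attached as attribute `audit`.
#' @export
filter_cohort <- function(events, min_days = 7, min_touches = 100) {
  by <- split(events$timestamp_ms, events$participant_id)
  span_days <- vapply(by, function(ts) (max(ts) - min(ts)) / 86400000,
                      numeric(1))
  n_touch <- vapply(by, length, integer(1))
  audit <- data.frame(participant_id = names(by),
                      span_days = unname(span_days),
                      n_touches = unname(n_touch),
                      retained = unname(span_days >= min_days &
                                          n_touch >= min_touches),
                      stringsAsFactors = FALSE)
  keep <- audit$participant_id[audit$retained]
  out <- events[events$participant_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Restrict events to a window around a cognitive test day
#'
#' Keeps events whose timestamp lies within `window_days` days on either
#' side of `test_day_ms` (both ends inclusive). A participant with no
#' event in the window is flagged for exclusion from that test's
#' regression.
#'
#' @param events Event table.
#' @param test_day_ms Test day as epoch milliseconds.
#' @param window_days Half width of the window in days (default 10).
#' @return Windowed event table; attribute `excluded` lists participant
#'   ids present in `events` but absent from the window.
#' @export
window_around_test <- function(events, test_day_ms, window_days = 10) {
  half <- window_days * 86400000
  keep <- events$timestamp_ms >= (test_day_ms - half) &
    events$timestamp_ms <= (test_day_ms + half)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <-
    setdiff(unique(events$participant_id), unique(out$participant_id))
  out
}
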