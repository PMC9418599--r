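#' Pipeline run configuration
#'
#' Bundles the knobs shared by the three analyses: the JID grid/kernel,
#' the bootstrap count and significance levels, the social app list and
#' the RNG seed. Every artifact produced under this configuration
#' carries it in its metadata.
#'
#' @param jid A [jid_config()].
#' @param n_boot Cluster bootstrap count (default 1000, as in the
#'   reference analysis; tests scale this down).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param cf_alpha Cluster-forming per-bin threshold (default 0.05).
#' @param fdr_alpha FDR level for residual pairs (default 0.001).
#' @param min_dist Minimum pair distance in bins (default 5).
#' @param r2_min Minimum pair R-squared (default 0.1).
#' @param window_days Half-width of the test window (default 10).
#' @param min_n Minimum cohort size for any regression (default 20).
#' @param min_days,min_touches Cohort inclusion filter (defaults 7 days,
#'   100 touches).
#' @param seed RNG seed for the bootstrap.
#' @param connectivity Cluster connectivity, 4 or 8 (default 8).
#' @return Object of class `run_config`.
#' @export
run_config <- function(jid = jid_config(), n_boot = 1000, alpha = 0.05,
                       cf_alpha = 0.05, fdr_alpha = 0.001, min_dist = 5,
                       r2_min = 0.1, window_days = 10, min_n = 20,
                       min_days = 7, min_touches = 100, seed = 1,
                       connectivity = 8) {
  stopifnot(inherits(jid, "jid_config"))
  structure(list(jid = jid, n_boot = n_boot, alpha = alpha,
                 cf_alpha = cf_alpha, fdr_alpha = fdr_alpha,
                 min_dist = min_dist, r2_min = r2_min,
                 window_days = window_days, min_n = min_n,
                 min_days = min_days, min_touches = min_touches,
                 seed = seed, connectivity = connectivity),
            class = "run_config")
}

# Vectorized equivalent of extract_itis + select_pairs over all sessions
# of one participant: ts/apps sorted, sid the session index per touch.
# Tested for equality against the public per-session route.
session_pairs_fast <- function(ts, apps, sid, config) {
  n <- length(ts)
  none <- data.frame(k = numeric(0), k_plus_1 = numeric(0))
  if (n < 2L) return(none)
  valid <- sid[-1L] == sid[-n]          # interval within one session
  v <- diff(ts)[valid]
  if (length(v) == 0L) return(none)
  lead <- apps[-n][valid]
  trail <- apps[-1L][valid]
  sess <- sid[-1L][valid]
  pos <- which(valid)                   # leading-touch index of each ITI
  if (config$variant == "transition") {
    tr <- lead != trail
    w <- v[tr]; s <- sess[tr]
    if (length(w) < 2L) return(none)
    ok <- s[-1L] == s[-length(s)]
    if (!any(ok)) return(none)
    return(data.frame(k = w[-length(w)][ok], k_plus_1 = w[-1L][ok]))
  }
  if (length(v) < 2L) return(none)
  adj <- pos[-1L] == pos[-length(pos)] + 1L  # consecutive raw intervals
  if (config$variant == "social") {
    soc <- config$social_apps
    nl <- length(v)
    adj <- adj & lead[-nl] %in% soc & trail[-nl] %in% soc &
      trail[-1L] %in% soc
  }
  if (!any(adj)) return(none)
  data.frame(k = v[-length(v)][adj], k_plus_1 = v[-1L][adj])
}

#' Build one JID per participant from raw events and episodes
#'
#' Segments sessions, extracts intervals, selects variant pairs and
#' computes the JID for every participant present in `events` (via a
#' vectorized path equivalent to [extract_itis()] + [select_pairs()]).
#' Participants yielding zero eligible pairs are skipped and listed in
#' the audit.
#'
#' @param events Event table.
#' @param episodes Episode table.
#' @param config A [jid_config()].
#' @return Named list of `jid` objects; attribute `audit` is a
#'   data.frame with per-participant pair counts and a `skipped` flag.
#' @export
participant_jids <- function(events, episodes, config = jid_config()) {
  events <- collapse_duplicate_touches(sort_events(events))
  episodes <- normalize_episodes(episodes)
  out <- list()
  audit <- list()
  for (pid in unique(events$participant_id)) {
    ev <- events[events$participant_id == pid, , drop = FALSE]
    ep <- episodes[episodes$participant_id == pid, , drop = FALSE]
    pairs <- NULL
    if (nrow(ep) > 0L) {
      idx <- findInterval(ev$timestamp_ms, ep$on_ms)
      inside <- idx >= 1L & ev$timestamp_ms <= ep$off_ms[pmax(idx, 1L)]
      if (any(inside)) {
        pairs <- session_pairs_fast(ev$timestamp_ms[inside],
                                    ev$app_id[inside], idx[inside],
                                    config)
      }
    }
    if (is.null(pairs) || nrow(pairs) == 0L) {
      audit[[pid]] <- data.frame(participant_id = pid, n_pairs = 0L,
                                 skipped = TRUE)
      next
    }
    out[[pid]] <- compute_jid(pairs, config)
    audit[[pid]] <- data.frame(participant_id = pid,
                               n_pairs = nrow(pairs), skipped = FALSE)
  }
  attr(out, "audit") <- do.call(rbind, audit)
  out
}

align_cohort <- function(jids, participants) {
  keep <- intersect(names(jids), participants$participant_id)
  meta <- participants[match(keep, participants$participant_id), ,
                       drop = FALSE]
  list(jids = jids[keep], meta = meta)
}

#' Age analysis: mass univariate age + gender model over all bins
#'
#' Applies the cohort filter, builds per-participant JIDs from the whole
#' recording, regresses every bin on age and gender with robust IRLS,
#' and corrects across bins with the 2-D cluster bootstrap.
#'
#' @param cohort A `tap_cohort` (or any list with `events`, `episodes`,
#'   `participants`).
#' @param config A [run_config()].
#' @return List with `stats` (`bin_stats`), `clusters`
#'   (`cluster_result`), `response`, `design`, `participants_used`,
#'   `audit`, `config`.
#' @export
run_age_analysis <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  events <- filter_cohort(cohort$events, config$min_days,
                          config$min_touches)
  jids <- participant_jids(events, cohort$episodes, config$jid)
  al <- align_cohort(jids, cohort$participants)
  if (length(al$jids) < config$min_n) {
    stop(sprintf("age analysis needs >= %d participants, have %d",
                 config$min_n, length(al$jids)), call. = FALSE)
  }
  Y <- build_response(al$jids)
  X <- cbind(age = al$meta$age_years, gender = al$meta$gender)
  stats <- mass_univariate(Y, X)
  clusters <- cluster_correct(stats, Y, X, predictor = "age",
                              n_boot = config$n_boot,
                              alpha = config$alpha, seed = config$seed,
                              cf_alpha = config$cf_alpha,
                              connectivity = config$connectivity)
  list(stats = stats, clusters = clusters, response = Y, design = X,
       participants_used = al$meta$participant_id,
       audit = list(cohort_filter = attr(events, "audit"),
                    jid = attr(jids, "audit")),
       config = config)
}

score_column <- function(task) {
  switch(task, srt = "srt_median_ms", crt = "crt_median_ms",
         global_cost = "global_cost", local_cost = "local_cost",
         corsi = "corsi_span", nback = "nback_dprime",
         stop("unknown cognitive task: ", task, call. = FALSE))
}

valid_column <- function(task) {
  switch(task, srt = "srt_valid", crt = "crt_valid",
         global_cost = "switch_valid", local_cost = "switch_valid",
         corsi = "corsi_valid", nback = "nback_valid")
}

day_column <- function(task) {
  switch(task, srt = "srt_day_ms", crt = "crt_day_ms",
         global_cost = "switch_day_ms", local_cost = "switch_day_ms",
         corsi = "corsi_day_ms", nback = "nback_day_ms")
}

#' Cognitive analysis: test score + gender model on windowed JIDs
#'
#' Scores the trial records, keeps participants passing the per-task
#' minimum-trial rule, restricts each participant's events to the window
#' around their test day, and runs the mass univariate regression of
#' every bin on the score and gender with cluster correction.
#' Participants lacking windowed smartphone data are excluded with an
#' audit entry. When no participant qualifies the function returns an
#' empty report (element `empty = TRUE`) rather than failing.
#'
#' @param cohort A `tap_cohort`-like list with `events`, `episodes`,
#'   `participants`, `trials`.
#' @param config A [run_config()].
#' @param task One of `"srt"`, `"crt"`, `"global_cost"`,
#'   `"local_cost"`, `"corsi"`, `"nback"`.
#' @return As [run_age_analysis()], plus `scores` and `task`; or an
#'   empty report.
#' @export
run_cognitive_analysis <- function(cohort, config = run_config(),
                                   task = "crt") {
  stopifnot(inherits(config, "run_config"))
  sc_col <- score_column(task)
  scores <- score_participants(cohort$trials)
  ok <- scores[[valid_column(task)]] & !is.na(scores[[sc_col]])
  scores <- scores[ok, , drop = FALSE]
  events <- filter_cohort(cohort$events, config$min_days,
                          config$min_touches)
  jids <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(scores))) {
    pid <- scores$participant_id[i]
    ev <- events[events$participant_id == pid, , drop = FALSE]
    ev <- window_around_test(ev, scores[[day_column(task)]][i],
                             config$window_days)
    if (nrow(ev) == 0L) {
      excluded <- c(excluded, pid)
      next
    }
    jl <- participant_jids(ev, cohort$episodes, config$jid)
    if (is.null(jl[[pid]])) {
      excluded <- c(excluded, pid)
      next
    }
    jids[[pid]] <- jl[[pid]]
  }
  scores <- scores[scores$participant_id %in% names(jids), , drop = FALSE]
  if (length(jids) < config$min_n) {
    return(list(empty = TRUE, task = task, n_available = length(jids),
                excluded = excluded, config = config))
  }
  Y <- build_response(jids)
  X <- cbind(score = scores[[sc_col]],
             gender = cohort$participants$gender[
               match(scores$participant_id,
                     cohort$participants$participant_id)])
  stats <- mass_univariate(Y, X)
  clusters <- cluster_correct(stats, Y, X, predictor = "score",
                              n_boot = config$n_boot,
                              alpha = config$alpha, seed = config$seed,
                              cf_alpha = config$cf_alpha,
                              connectivity = config$connectivity)
  list(empty = FALSE, task = task, scores = scores, stats = stats,
       clusters = clusters, response = Y, design = X,
       participants_used = scores$participant_id,
       excluded = excluded, config = config)
}

#' Residual-pair analysis: the pace-of-aging map
#'
#' Runs (or reuses) the age analysis, residualizes the significant bins
#' in two steps (gender, then age), and classifies all far-apart bin
#' pairs as consistent or inconsistent aging.
#'
#' @param cohort A `tap_cohort`.
#' @param config A [run_config()].
#' @param age_bundle Optional result of [run_age_analysis()] to reuse.
#' @return List with `residuals` (`residual_matrix`), `pairs`
#'   (classification table), `r2_maps`, `age_bundle`, `config`.
#' @export
run_residual_analysis <- function(cohort, config = run_config(),
                                  age_bundle = NULL) {
  if (is.null(age_bundle)) {
    age_bundle <- run_age_analysis(cohort, config)
  }
  meta <- cohort$participants[
    match(age_bundle$participants_used,
          cohort$participants$participant_id), , drop = FALSE]
  res <- two_step_residuals(age_bundle$response, meta$gender,
                            meta$age_years,
                            age_bundle$clusters$sig_mask)
  pairs <- classify_pairs(res, min_dist = config$min_dist,
                          r2_min = config$r2_min,
                          alpha = config$fdr_alpha)
  maps <- pair_r2_maps(pairs, grid_dim = dim(age_bundle$clusters$sig_mask))
  list(residuals = res, pairs = pairs, r2_maps = maps,
       age_bundle = age_bundle, config = config)
}
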