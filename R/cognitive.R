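#' Minimum successfully-executed trials per task for a valid score
#' @keywords internal
trial_minima <- c(srt = 12L, crt = 24L, switch = 12L, corsi = 2L,
                  nback = 30L)

# A trial counts as "successfully executed" when a response was recorded
# in time (<= 3 s for RT tasks); correctness is not required for the
# inclusion minima, only for the medians.
executed_rt <- function(trials) {
  !is.na(trials$rt_ms) & trials$rt_ms <= 3000
}

#' Score a simple or choice reaction-time task
#'
#' The score is the median reaction time over correct trials. Validity
#' requires at least 12 (simple) or 24 (choice) successfully executed
#' trials; responses slower than 3 s count as executed but not correct.
#'
#' @param trials Trial records for one participant and one task, with
#'   columns `rt_ms` and `correct`.
#' @param task `"srt"` or `"crt"`.
#' @return List with `score` (median ms, `NA` if no correct trial),
#'   `valid`, `n_executed`.
#' @export
score_reaction_time <- function(trials, task = c("srt", "crt")) {
  task <- match.arg(task)
  exec <- executed_rt(trials)
  ok <- exec & trials$correct
  score <- if (any(ok)) median(trials$rt_ms[ok]) else NA_real_
  list(score = score,
       valid = sum(exec) >= trial_minima[[task]] && any(ok),
       n_executed = sum(exec))
}

#' Score the cued task-switching test
#'
#' Global cost is the relative slowing of mixed blocks over the pure
#' shape/color blocks, normalized by the pure-block median; local cost is
#' the relative slowing of switch over non-switch trials within mixed
#' blocks, normalized by the non-switch median. Correct trials only.
#'
#' @param trials Trial records with `rt_ms`, `correct`, `block_type`
#'   (`"pure_shape"`, `"pure_color"`, `"mixed"`) and `is_switch_trial`.
#' @return List with `global_cost`, `local_cost`, `valid`, `n_executed`.
#' @export
score_task_switch <- function(trials) {
  exec <- executed_rt(trials)
  ok <- exec & trials$correct
  pure <- ok & trials$block_type %in% c("pure_shape", "pure_color")
  mixed <- ok & trials$block_type == "mixed"
  valid <- sum(exec) >= trial_minima[["switch"]]
  if (!any(pure) || !any(mixed)) {
    return(list(global_cost = NA_real_, local_cost = NA_real_,
                valid = FALSE, n_executed = sum(exec)))
  }
  med_pure <- median(trials$rt_ms[pure])
  med_mixed <- median(trials$rt_ms[mixed])
  global_cost <- (med_mixed - med_pure) / med_pure
  sw <- mixed & trials$is_switch_trial
  ns <- mixed & !trials$is_switch_trial
  local_cost <- if (any(sw) && any(ns)) {
    med_ns <- median(trials$rt_ms[ns])
    (median(trials$rt_ms[sw]) - med_ns) / med_ns
  } else NA_real_
  list(global_cost = global_cost, local_cost = local_cost,
       valid = valid && !is.na(local_cost), n_executed = sum(exec))
}

#' Score the Corsi block-tapping task
#'
#' The span is the longest sequence length correctly reproduced before
#' the task terminated (two consecutive errors, or all 9 positions
#' correct). Trials after the first two consecutive errors are ignored.
#'
#' @param trials Trial records in presentation order with
#'   `sequence_length` and `correct`.
#' @return List with `span` (0 if no length was passed), `valid`,
#'   `n_trials`.
#' @export
score_corsi <- function(trials) {
  n <- nrow(trials)
  span <- 0L
  consec_err <- 0L
  for (i in seq_len(n)) {
    if (isTRUE(trials$correct[i])) {
      consec_err <- 0L
      span <- max(span, trials$sequence_length[i])
      if (span >= 9L) break
    } else {
      consec_err <- consec_err + 1L
      if (consec_err >= 2L) break
    }
  }
  list(span = as.integer(span), valid = n >= trial_minima[["corsi"]],
       n_trials = n)
}

#' Score the 2-back task as d-prime
#'
#' Sensitivity d' = z(hit rate) - z(false-alarm rate). Extreme rates are
#' clipped to `[1/(2N), 1 - 1/(2N)]`, `N` the number of trials of that
#' class, so d' stays finite.
#'
#' @param trials Trial records with logical `is_target` and `responded`.
#' @return List with `dprime`, `hit_rate`, `fa_rate` (post-clip),
#'   `valid`, `n_trials`.
#' @export
score_nback <- function(trials) {
  n <- nrow(trials)
  n_t <- sum(trials$is_target)
  n_nt <- sum(!trials$is_target)
  if (n_t == 0L) {
    return(list(dprime = NA_real_, hit_rate = NA_real_,
                fa_rate = NA_real_, valid = FALSE, n_trials = n))
  }
  clip <- function(r, N) min(max(r, 1 / (2 * N)), 1 - 1 / (2 * N))
  hr <- clip(sum(trials$responded & trials$is_target) / n_t, n_t)
  far <- if (n_nt > 0L) {
    clip(sum(trials$responded & !trials$is_target) / n_nt, n_nt)
  } else 0.5
  list(dprime = qnorm(hr) - qnorm(far), hit_rate = hr, fa_rate = far,
       valid = n >= trial_minima[["nback"]], n_trials = n)
}

#' The eight finger-posture images, in canonical order
#' @export
finger_postures <- c("left_thumb", "right_thumb", "both_thumbs_portrait",
                     "both_thumbs_landscape", "left_index", "right_index",
                     "left_middle", "right_middle")

#' Convert finger-preference ranks to the two 0-1 scales
#'
#' Participants rank the eight posture images from most used (1) to
#' least used (8). Each scale takes the best (lowest) rank `r*` among its
#' image set and maps it to `(8 - r*) / 7`, so 1 means most preferred and
#' 0 least. The thumb scale uses the four thumb images; the dual-thumb
#' scale uses the two both-thumbs images.
#'
#' @param ranks Named integer vector: a permutation of 1..8 with names
#'   from [finger_postures].
#' @return List with `thumb_pref` and `dual_thumb_pref`, both in
#'   `[0, 1]`.
#' @export
finger_scales <- function(ranks) {
  if (!setequal(names(ranks), finger_postures) ||
      !setequal(as.integer(ranks), 1:8)) {
    stop("ranks must be a named permutation of 1..8 over the 8 postures",
         call. = FALSE)
  }
  thumb_set <- c("left_thumb", "right_thumb", "both_thumbs_portrait",
                 "both_thumbs_landscape")
  dual_set <- c("both_thumbs_portrait", "both_thumbs_landscape")
  sc <- function(set) (8 - min(ranks[set])) / 7
  list(thumb_pref = sc(thumb_set), dual_thumb_pref = sc(dual_set))
}

#' Score all cognitive tasks for every participant
#'
#' Applies the per-task scorers to a trial table covering multiple
#' participants and tasks, enforcing the per-task minimum-trial rules.
#'
#' @param trials Trial table with a `participant_id` and `task` column
#'   plus the task-specific fields (see [score_reaction_time()],
#'   [score_task_switch()], [score_corsi()], [score_nback()]).
#' @return `data.frame`, one row per participant: scores and
#'   `*_valid` flags, plus `test_day_ms` per task when present.
#' @export
score_participants <- function(trials) {
  res <- lapply(split(trials, trials$participant_id), function(tr) {
    pick <- function(task) tr[tr$task == task, , drop = FALSE]
    srt <- score_reaction_time(pick("srt"), "srt")
    crt <- score_reaction_time(pick("crt"), "crt")
    sw <- score_task_switch(pick("switch"))
    co <- score_corsi(pick("corsi"))
    nb <- score_nback(pick("nback"))
    day <- function(task) {
      d <- pick(task)$test_day_ms
      if (length(d)) d[1] else NA_real_
    }
    data.frame(participant_id = tr$participant_id[1],
               srt_median_ms = srt$score, srt_valid = srt$valid,
               crt_median_ms = crt$score, crt_valid = crt$valid,
               global_cost = sw$global_cost, local_cost = sw$local_cost,
               switch_valid = sw$valid,
               corsi_span = co$span, corsi_valid = co$valid,
               nback_dprime = nb$dprime, nback_valid = nb$valid,
               srt_day_ms = day("srt"), crt_day_ms = day("crt"),
               switch_day_ms = day("switch"), corsi_day_ms = day("corsi"),
               nback_day_ms = day("nback"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
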