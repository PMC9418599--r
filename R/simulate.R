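#' Specification of a synthetic tappigraphy cohort
#'
#' The generator emulates the structure of a smartphone-aging study
#' sample: a bimodal age distribution (modes near 25 and 63 years,
#' truncated to 16-86), a female-biased gender split (62.5%), and
#' session-structured tap streams whose inter-touch intervals follow an
#' age-dependent two-component log-normal mixture anchored at ~100 ms
#' (fast taps, log10 mean 2.0) and ~4 s (slow taps, log10 mean 3.6). The
#' weight of the fast component declines linearly with age, so older
#' synthetic participants lose probability mass at short intervals and
#' gain it at long ones. A latent standard-normal "pace" factor per
#' participant loads positively on the fast-component weight and
#' negatively on the slow-component mean, planting correlated residual
#' structure across bins for the pair analysis. App labels follow a
#' two-state (social / non-social) Markov chain; cognitive trial records
#' carry linear age effects.
#'
#' @param n_participants Cohort size (default 60).
#' @param seed RNG seed driving every random quantity (default 1).
#' @param days Recording days per participant (default 14, comfortably
#'   above the 7-day inclusion cut-off).
#' @param age_modes,age_sds,age_weights Components of the bimodal age
#'   mixture (defaults: modes 25 and 63, sds 7 and 8, equal weights).
#' @param age_range Truncation range in years (default `c(16, 86)`).
#' @param p_female Probability of gender code 2 (default 0.625).
#' @param sessions_per_day Expected sessions per day at age 16
#'   (default 20).
#' @param sessions_age_slope Change in expected sessions/day per year of
#'   age (default -0.1; usage declines with age).
#' @param touches_mu,touches_size Negative-binomial parameters of
#'   touches per session beyond the minimum of 2 (defaults 15 and 2).
#' @param iti_means_log10 Fast and slow component means in log10 ms
#'   (default `c(2.0, 3.6)`).
#' @param iti_sds_log10 Component sds in log10 units
#'   (default `c(0.25, 0.35)`).
#' @param fast_weight_base Fast-component weight at age 16
#'   (default 0.75).
#' @param fast_weight_age_slope Decline of that weight per year
#'   (default 0.006); the weight is clipped to `[0.05, 0.95]`.
#' @param pace_loading Loading of the latent pace factor: `+pace_loading`
#'   on the fast weight, `-pace_loading` on the slow-component log10
#'   mean (default 0.05).
#' @param social_apps,other_apps App id pools (defaults: three social /
#'   browser apps, four others).
#' @param app_switch_prob Per-touch probability of switching the
#'   social/non-social state, which also changes the concrete app
#'   (default 0.1).
#' @param cognitive List of linear age models for the tests; see
#'   Details.
#' @details `cognitive` fields (all RTs in ms, slopes per year of age
#'   past 16): `srt_base` 270, `srt_slope` 1.0; `crt_base` 450,
#'   `crt_slope` 2.0; `pure_base` 550, `pure_slope` 2.0; `global_base`
#'   0.15, `global_slope` 0.002; `local_base` 0.08, `local_slope` 0.001;
#'   `corsi_base` 7, `corsi_slope` -0.04; `dprime_base` 2.8,
#'   `dprime_slope` -0.015; `rt_sdlog` 0.15 (log-normal trial noise).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 60, seed = 1, days = 14,
                        age_modes = c(25, 63), age_sds = c(7, 8),
                        age_weights = c(0.5, 0.5),
                        age_range = c(16, 86), p_female = 0.625,
                        sessions_per_day = 20,
                        sessions_age_slope = -0.1,
                        touches_mu = 15, touches_size = 2,
                        iti_means_log10 = c(2.0, 3.6),
                        iti_sds_log10 = c(0.25, 0.35),
                        fast_weight_base = 0.75,
                        fast_weight_age_slope = 0.006,
                        pace_loading = 0.05,
                        social_apps = c("social_a", "social_b",
                                        "browser_a"),
                        other_apps = c("game_a", "mail_a", "news_a",
                                       "maps_a"),
                        app_switch_prob = 0.1,
                        cognitive = list()) {
  cog <- list(srt_base = 270, srt_slope = 1.0,
              crt_base = 450, crt_slope = 2.0,
              pure_base = 550, pure_slope = 2.0,
              global_base = 0.15, global_slope = 0.002,
              local_base = 0.08, local_slope = 0.001,
              corsi_base = 7, corsi_slope = -0.04,
              dprime_base = 2.8, dprime_slope = -0.015,
              rt_sdlog = 0.15)
  cog[names(cognitive)] <- cognitive
  spec <- list(n_participants = as.integer(n_participants), seed = seed,
               days = days, age_modes = age_modes, age_sds = age_sds,
               age_weights = age_weights, age_range = age_range,
               p_female = p_female, sessions_per_day = sessions_per_day,
               sessions_age_slope = sessions_age_slope,
               touches_mu = touches_mu, touches_size = touches_size,
               iti_means_log10 = iti_means_log10,
               iti_sds_log10 = iti_sds_log10,
               fast_weight_base = fast_weight_base,
               fast_weight_age_slope = fast_weight_age_slope,
               pace_loading = pace_loading,
               social_apps = social_apps, other_apps = other_apps,
               app_switch_prob = app_switch_prob, cognitive = cog)
  if (spec$n_participants < 1) stop("need at least one participant",
                                    call. = FALSE)
  if (spec$sessions_per_day <= 0) stop("sessions_per_day must be > 0",
                                       call. = FALSE)
  if (spec$days <= 0) stop("days must be > 0", call. = FALSE)
  if (any(c(p_female, app_switch_prob) < 0) ||
      any(c(p_female, app_switch_prob) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

# Fast-component mixture weight as a function of age and pace factor z.
fast_weight <- function(spec, age, z = 0) {
  pmin(pmax(spec$fast_weight_base -
              spec$fast_weight_age_slope * (age - 16) +
              spec$pace_loading * z, 0.05), 0.95)
}

draw_ages <- function(spec, n) {
  comp <- sample.int(2L, n, replace = TRUE, prob = spec$age_weights)
  age <- rnorm(n, spec$age_modes[comp], spec$age_sds[comp])
  # redraw out-of-range ages (truncation, not clipping)
  bad <- which(age < spec$age_range[1] | age > spec$age_range[2])
  while (length(bad) > 0L) {
    comp2 <- sample.int(2L, length(bad), replace = TRUE,
                        prob = spec$age_weights)
    age[bad] <- rnorm(length(bad), spec$age_modes[comp2],
                      spec$age_sds[comp2])
    bad <- which(age < spec$age_range[1] | age > spec$age_range[2])
  }
  age
}

# Per-session app label chain: two-state Markov (social / non-social);
# the concrete app changes at every state switch.
draw_apps <- function(spec, n_touch) {
  switch_here <- c(TRUE, runif(n_touch - 1) < spec$app_switch_prob)
  seg <- cumsum(switch_here)
  n_seg <- seg[n_touch]
  state0 <- runif(1) < 0.5
  states <- xor(state0, (seq_len(n_seg) %% 2L) == 0L)  # alternate
  seg_app <- ifelse(states,
                    sample(spec$social_apps, n_seg, replace = TRUE),
                    sample(spec$other_apps, n_seg, replace = TRUE))
  seg_app[seg]
}

draw_session_itis <- function(spec, n_iti, w_fast, slow_mu) {
  fast <- runif(n_iti) < w_fast
  mu <- ifelse(fast, spec$iti_means_log10[1], slow_mu)
  sdv <- ifelse(fast, spec$iti_sds_log10[1], spec$iti_sds_log10[2])
  10^rnorm(n_iti, mu, sdv)
}

#' Generate a synthetic cohort
#'
#' Draws participants, session-structured touch events with screen
#' episodes, trial-level cognitive records and the planted ground truth,
#' all from the single seed in the spec (so a fixed spec reproduces the
#' cohort byte for byte).
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `tap_cohort`: list with `participants`
#'   (metadata incl. finger scales), `events`, `episodes`, `trials`,
#'   `truth` (see [planted_truth()], plus the per-participant
#'   `pace_factor`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  pid <- sprintf("P%04d", seq_len(n))
  age <- draw_ages(spec, n)
  gender <- ifelse(runif(n) < spec$p_female, 2L, 1L)
  z <- rnorm(n)  # latent pace factor
  # finger preference: younger participants tend to prefer thumbs
  thumb_first <- runif(n) < pmin(pmax(0.9 - 0.006 * (age - 16), 0.1), 0.95)
  ranks <- lapply(seq_len(n), function(i) {
    pr <- sample(finger_postures)
    if (thumb_first[i] && !pr[1] %in% finger_postures[1:4]) {
      j <- which(pr %in% finger_postures[1:4])[1]
      pr[c(1, j)] <- pr[c(j, 1)]
    }
    setNames(match(finger_postures, pr), finger_postures)
  })
  scales <- lapply(ranks, finger_scales)
  participants <- data.frame(
    participant_id = pid, age_years = age, gender = gender,
    thumb_pref = vapply(scales, `[[`, numeric(1), "thumb_pref"),
    dual_thumb_pref = vapply(scales, `[[`, numeric(1),
                             "dual_thumb_pref"),
    years_smartphone = pmin(pmax(rnorm(n, 14 - 0.05 * (age - 16), 3), 1),
                            25),
    screen_size_inch = round(rnorm(n, 5.8, 0.6), 1),
    stringsAsFactors = FALSE)

  day_ms <- 86400000
  ev <- vector("list", n)
  epi <- vector("list", n)
  for (i in seq_len(n)) {
    w <- fast_weight(spec, age[i], z[i])
    slow_mu <- spec$iti_means_log10[2] - spec$pace_loading * z[i]
    lambda <- max(2, spec$sessions_per_day +
                    spec$sessions_age_slope * (age[i] - 16))
    ts_all <- list(); app_all <- list(); on_all <- off_all <- numeric(0)
    for (d in seq_len(spec$days) - 1L) {
      n_sess <- rpois(1, lambda)
      cursor <- d * day_ms
      day_end <- (d + 1) * day_ms
      for (s in seq_len(n_sess)) {
        gap <- runif(1, 30e3, 600e3)
        on <- cursor + gap
        if (on >= day_end) break
        n_touch <- 2L + rnbinom(1, size = spec$touches_size,
                                mu = spec$touches_mu)
        itis <- draw_session_itis(spec, n_touch - 1L, w, slow_mu)
        ts <- on + 200 + cumsum(c(0, itis))
        apps <- draw_apps(spec, n_touch)
        off <- ts[n_touch] + 500
        ts_all[[length(ts_all) + 1L]] <- ts
        app_all[[length(app_all) + 1L]] <- apps
        on_all <- c(on_all, on)
        off_all <- c(off_all, off)
        cursor <- off
        if (cursor >= day_end) break
      }
    }
    ts <- unlist(ts_all)
    ev[[i]] <- data.frame(participant_id = pid[i],
                          timestamp_ms = round(ts),
                          app_id = unlist(app_all),
                          stringsAsFactors = FALSE)
    epi[[i]] <- data.frame(participant_id = pid[i],
                           on_ms = floor(on_all), off_ms = ceiling(off_all),
                           stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  episodes <- do.call(rbind, epi)
  events <- collapse_duplicate_touches(sort_events(events))
  rownames(events) <- rownames(episodes) <- NULL

  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_trials(spec, pid[i], age[i], test_day_ms = 7 * day_ms)
  }))
  rownames(trials) <- NULL

  truth <- planted_truth(spec)
  truth$pace_factor <- setNames(z, pid)
  structure(list(participants = participants, events = events,
                 episodes = episodes, trials = trials, truth = truth,
                 spec = spec),
            class = "tap_cohort")
}

# Trial-level cognitive records with linear age effects.
simulate_trials <- function(spec, pid, age, test_day_ms) {
  cg <- spec$cognitive
  a <- age - 16
  lnrt <- function(n, mean_ms) {
    mean_ms * exp(rnorm(n, 0, cg$rt_sdlog))
  }
  blank <- function(n) rep(NA, n)
  row0 <- function(task, n, rt, correct, block = "none",
                   is_switch = blank(n), seq_len_ = blank(n),
                   is_target = blank(n), responded = blank(n)) {
    data.frame(participant_id = pid, task = task,
               trial_index = seq_len(n), rt_ms = rt, correct = correct,
               block_type = block, is_switch_trial = is_switch,
               sequence_length = seq_len_, is_target = is_target,
               responded = responded, test_day_ms = test_day_ms,
               stringsAsFactors = FALSE)
  }
  # simple (25 trials) and choice (50 trials) reaction time
  srt_rt <- lnrt(25, cg$srt_base + cg$srt_slope * a)
  srt <- row0("srt", 25, srt_rt, runif(25) < 0.97 & srt_rt <= 3000)
  crt_rt <- lnrt(50, cg$crt_base + cg$crt_slope * a)
  crt <- row0("crt", 50, crt_rt, runif(50) < 0.94 & crt_rt <= 3000)
  # task switching: 4 pure blocks of 20, 2 mixed blocks of 50
  pure_mean <- cg$pure_base + cg$pure_slope * a
  gc <- cg$global_base + cg$global_slope * a
  lc <- cg$local_base + cg$local_slope * a
  n_pure <- 80; n_mixed <- 100
  pure_rt <- lnrt(n_pure, pure_mean)
  pure <- row0("switch", n_pure, pure_rt, runif(n_pure) < 0.95,
               block = rep(c("pure_shape", "pure_color"),
                           each = n_pure / 2))
  is_sw <- runif(n_mixed) < 0.5
  mixed_mean <- pure_mean * (1 + gc) * ifelse(is_sw, 1 + lc, 1)
  mixed_rt <- mixed_mean * exp(rnorm(n_mixed, 0, cg$rt_sdlog))
  mixed <- row0("switch", n_mixed, mixed_rt, runif(n_mixed) < 0.93,
                block = "mixed", is_switch = is_sw)
  mixed$trial_index <- mixed$trial_index + n_pure
  # Corsi: two trials per length from 2 upward, stop on two consecutive
  # errors or at 9
  span_true <- min(max(cg$corsi_base + cg$corsi_slope * a, 2), 9)
  lens <- integer(0); corr <- logical(0)
  consec <- 0L
  for (len in 2:9) {
    done <- FALSE
    for (rep_ in 1:2) {
      p_ok <- plogis(2.5 * (span_true - len + 0.5))
      ok <- runif(1) < p_ok
      lens <- c(lens, len); corr <- c(corr, ok)
      consec <- if (ok) 0L else consec + 1L
      if (consec >= 2L) { done <- TRUE; break }
    }
    if (done || (len == 9L && any(corr[lens == 9L]))) break
  }
  corsi <- row0("corsi", length(lens), blank(length(lens)), corr,
                seq_len_ = lens)
  # 2-back: 3 blocks of 30, 30% targets; performance set by d'(age)
  dp <- max(cg$dprime_base + cg$dprime_slope * a, 0.2)
  n_nb <- 90
  is_t <- runif(n_nb) < 0.3
  resp <- ifelse(is_t, runif(n_nb) < pnorm(dp / 2),
                 runif(n_nb) < pnorm(-dp / 2))
  nback <- row0("nback", n_nb, blank(n_nb), resp == is_t,
                is_target = is_t, responded = resp)
  rbind(srt, crt, pure, mixed, corsi, nback)
}

#' Planted ground truth of the synthetic cohort
#'
#' Derives, deterministically from the spec, the expected direction of
#' the age effect and of the pace-factor loading at every grid bin. The
#' expected JID under the generator factorizes over the two grid axes
#' (consecutive intervals are independent draws from the mixture), so
#' the expected bin mass is an outer product of the KDE-smoothed mixture
#' marginal with itself; age and pace derivatives are taken numerically.
#'
#' @param spec A [cohort_spec()].
#' @param config Grid configuration (default [jid_config()]).
#' @param eps Step for the numeric derivatives (default age 1 year,
#'   pace 0.1 sd).
#' @return List with `age_sign` and `pace_sign` (grid matrices in
#'   {-1, 0, 1}; derivatives below `tol` count as 0), `expected_mass`
#'   at the cohort mean age, `fast_region` and `slow_region` (logical
#'   grids flagging bins within 0.25 log10 of the fast-fast and
#'   slow-slow anchors), and the true cognitive age slopes.
#' @export
planted_truth <- function(spec, config = jid_config(), eps = 1) {
  b <- jid_bins(config)
  marginal <- function(age, z) {
    w <- fast_weight(spec, age, z)
    slow_mu <- spec$iti_means_log10[2] - spec$pace_loading * z
    sds <- sqrt(spec$iti_sds_log10^2 + config$bandwidth^2)
    w * dnorm(b$centers, spec$iti_means_log10[1], sds[1]) +
      (1 - w) * dnorm(b$centers, slow_mu, sds[2])
  }
  expected_grid <- function(age, z) {
    m <- marginal(age, z)
    g <- outer(m, m)
    g / sum(g)
  }
  age_mid <- mean(spec$age_range)
  g_lo <- expected_grid(age_mid - eps, 0)
  g_hi <- expected_grid(age_mid + eps, 0)
  d_age <- (g_hi - g_lo) / (2 * eps)
  gz_lo <- expected_grid(age_mid, -0.1)
  gz_hi <- expected_grid(age_mid, 0.1)
  d_pace <- (gz_hi - gz_lo) / 0.2
  tol <- 1e-8
  sgn <- function(d) ifelse(abs(d) < tol, 0L, ifelse(d > 0, 1L, -1L))
  region <- function(center) {
    near <- abs(b$centers - center) <= 0.25
    outer(near, near, "&")
  }
  cg <- spec$cognitive
  list(age_sign = sgn(d_age), pace_sign = sgn(d_pace),
       expected_mass = expected_grid(age_mid, 0),
       fast_region = region(spec$iti_means_log10[1]),
       slow_region = region(spec$iti_means_log10[2]),
       cognitive_slopes = c(srt = cg$srt_slope, crt = cg$crt_slope,
                            global_cost = cg$global_slope,
                            local_cost = cg$local_slope,
                            corsi = cg$corsi_slope,
                            dprime = cg$dprime_slope))
}

#' Expected consistency label for a planted pair of bins
#'
#' Under the generator, the residual coupling between two bins is driven
#' by the shared pace factor, so the expected correlation sign is the
#' product of the pace-loading signs and the expected age-slope sign is
#' the planted age sign; the label follows the same triple-product rule
#' as [classify_pairs()].
#'
#' @param truth Output of [planted_truth()].
#' @param i,j Bin indices as `c(row, col)` pairs.
#' @return `"consistent"`, `"inconsistent"`, or `NA` when any involved
#'   sign is 0.
#' @export
expected_pair_label <- function(truth, i, j) {
  si <- truth$age_sign[i[1], i[2]]; sj <- truth$age_sign[j[1], j[2]]
  gi <- truth$pace_sign[i[1], i[2]]; gj <- truth$pace_sign[j[1], j[2]]
  if (si == 0 || sj == 0 || gi == 0 || gj == 0) return(NA_character_)
  if (gi * gj * si * sj > 0) "consistent" else "inconsistent"
}

#' A fixed six-touch session for documentation and tests
#'
#' Returns a single-session stream of six touches (so five inter-touch
#' intervals and four consecutive joint pairs) together with its screen
#' episode.
#'
#' @return List with `events` and `episodes` tables for one participant.
#' @export
worked_example_stream <- function() {
  ts <- c(0, 120, 250, 2250, 2405, 9405)
  list(events = data.frame(participant_id = "demo",
                           timestamp_ms = ts,
                           app_id = c("social_a", "social_a", "social_a",
                                      "mail_a", "mail_a", "mail_a"),
                           stringsAsFactors = FALSE),
       episodes = data.frame(participant_id = "demo",
                             on_ms = -100, off_ms = 9905,
                             stringsAsFactors = FALSE))
}

#' Write a generated cohort to CSV/JSON files
#'
#' @param cohort A `tap_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(cohort$events, file.path(dir, "events.csv"))
  write.csv(cohort$episodes, file.path(dir, "episodes.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$participants, file.path(dir, "participants.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$trials, file.path(dir, "trials.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$age_sign <- as.vector(truth$age_sign)
  truth$pace_sign <- as.vector(truth$pace_sign)
  truth$expected_mass <- as.vector(truth$expected_mass)
  truth$fast_region <- as.vector(truth$fast_region)
  truth$slow_region <- as.vector(truth$slow_region)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
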