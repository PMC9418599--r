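# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately written as plain loops / closed forms so they
# share no code path with the package implementation.

# Brute-force kernel-sum oracle for the JID: loops over bins and sums
# the bivariate Gaussian kernel over all pairs, then normalizes.
oracle_jid <- function(pairs, config = jid_config()) {
  edges <- seq(config$log10_range_ms[1], config$log10_range_ms[2],
               length.out = config$n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  h <- config$bandwidth
  lx <- log10(pairs$k)
  ly <- log10(pairs$k_plus_1)
  g <- matrix(0, config$n_bins, config$n_bins)
  for (i in seq_len(config$n_bins)) {
    for (j in seq_len(config$n_bins)) {
      g[i, j] <- sum(exp(-((centers[i] - lx)^2 + (centers[j] - ly)^2) /
                           (2 * h^2)))
    }
  }
  g / sum(g)
}

# Closed-form OLS via the normal equations (no lm).
oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# One bisquare IRLS step at given coefficients: residuals -> MAD scale ->
# weights -> weighted normal equations, all in base R.
oracle_irls_step <- function(y, X, beta, tune = 4.685) {
  Xi <- cbind(1, X)
  r <- as.vector(y - Xi %*% beta)
  s <- median(abs(r)) / 0.6745
  u <- r / (tune * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  solve(t(Xi * w) %*% Xi, t(Xi * w) %*% y)[, 1]
}

# A tiny deterministic event/episode fixture: two participants, two
# sessions each, known intervals.
fixture_two_participants <- function() {
  ev <- rbind(
    data.frame(participant_id = "a",
               timestamp_ms = c(0, 100, 350, 10000, 10100, 10400),
               app_id = c("s1", "s1", "s1", "x", "x", "x")),
    data.frame(participant_id = "b",
               timestamp_ms = c(50, 250, 20050, 20300),
               app_id = c("s1", "x", "x", "x")))
  ep <- rbind(
    data.frame(participant_id = "a", on_ms = c(-10, 9990),
               off_ms = c(500, 10500)),
    data.frame(participant_id = "b", on_ms = c(0, 20000),
               off_ms = c(1000, 21000)))
  list(events = ev, episodes = ep)
}

# A small synthetic cohort reused by several tests (generation is the
# slow part, so memoise it per session).
local_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(n_participants = 25,
                                            seed = 301, days = 8,
                                            sessions_per_day = 8))
    }
    cache
  }
})
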