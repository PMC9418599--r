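#' JID configuration
#'
#' Fixes the grid and kernel for the joint-interval distribution: 50 bins
#' per dimension over log10 intervals in `[0.5, 5]` (i.e. 10^0.5 ms to
#' 10^5 ms) and an isotropic Gaussian kernel with bandwidth 0.1 in log10
#' units. The `variant` selects which interval pairs enter the JID: all
#' pairs (`"full"`), pairs fully on configured social/browser apps
#' (`"social"`), or pairs of app-transition intervals (`"transition"`).
#'
#' @param n_bins Bins per dimension (default 50).
#' @param log10_range_ms Lower/upper grid edge in log10 ms
#'   (default `c(0.5, 5)`).
#' @param bandwidth Gaussian kernel bandwidth in log10 units
#'   (default 0.1).
#' @param variant One of `"full"`, `"social"`, `"transition"`.
#' @param social_apps Character vector of app ids counted as
#'   social-networking/browser apps (used by the `"social"` variant).
#' @return An object of class `jid_config`.
#' @export
jid_config <- function(n_bins = 50, log10_range_ms = c(0.5, 5),
                       bandwidth = 0.1, variant = "full",
                       social_apps = character()) {
  if (!is.numeric(n_bins) || n_bins < 2) {
    stop("n_bins must be >= 2", call. = FALSE)
  }
  if (length(log10_range_ms) != 2 ||
      log10_range_ms[1] >= log10_range_ms[2]) {
    stop("log10_range_ms must be an increasing pair", call. = FALSE)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be > 0", call. = FALSE)
  }
  if (!variant %in% c("full", "social", "transition")) {
    stop("unknown JID variant: ", variant, call. = FALSE)
  }
  structure(list(n_bins = as.integer(n_bins),
                 log10_range_ms = as.numeric(log10_range_ms),
                 bandwidth = bandwidth,
                 variant = variant,
                 social_apps = as.character(social_apps)),
            class = "jid_config")
}

#' Grid bin edges and centers in log10 ms
#' @param config A [jid_config()].
#' @return List with `edges` (n_bins + 1) and `centers` (n_bins).
#' @export
jid_bins <- function(config) {
  edges <- seq(config$log10_range_ms[1], config$log10_range_ms[2],
               length.out = config$n_bins + 1L)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

#' Select consecutive interval pairs for a JID variant
#'
#' Given per-session interval sequences (from [extract_itis()]), forms
#' the (k, k+1) pairs that feed [compute_jid()]:
#' * `full`: every consecutive pair of intervals within a session;
#' * `social`: consecutive pairs for which all three bounding touches
#'   were on configured social apps;
#' * `transition`: the sub-sequence of intervals whose leading and
#'   trailing touches differ in app, re-paired consecutively within the
#'   session.
#'
#' Pairs never span sessions.
#'
#' @param itis A single `data.frame` from [extract_itis()] or a list of
#'   them (one per session).
#' @param config A [jid_config()]; its `variant` and `social_apps` fields
#'   drive the selection.
#' @return `data.frame` with columns `k` and `k_plus_1` in ms.
#' @export
select_pairs <- function(itis, config) {
  stopifnot(inherits(config, "jid_config"))
  if (is.data.frame(itis)) itis <- list(itis)
  pick <- lapply(itis, function(seq) {
    v <- seq$iti_ms
    if (config$variant == "transition") {
      v <- v[seq$lead_app != seq$trail_app]
      if (length(v) < 2L) return(NULL)
      return(data.frame(k = v[-length(v)], k_plus_1 = v[-1L]))
    }
    if (length(v) < 2L) return(NULL)
    k <- v[-length(v)]
    k1 <- v[-1L]
    if (config$variant == "social") {
      soc <- config$social_apps
      # all three touches bounding the pair must be on social apps
      ok <- seq$lead_app[-length(v)] %in% soc &
        seq$trail_app[-length(v)] %in% soc &
        seq$trail_app[-1L] %in% soc
      k <- k[ok]; k1 <- k1[ok]
    }
    if (length(k) == 0L) return(NULL)
    data.frame(k = k, k_plus_1 = k1)
  })
  pick <- pick[!vapply(pick, is.null, logical(1))]
  if (length(pick) == 0L) {
    return(data.frame(k = numeric(0), k_plus_1 = numeric(0)))
  }
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}

#' Compute a joint-interval distribution
#'
#' Estimates the joint density of consecutive log10 inter-touch intervals
#' with an isotropic 2-D Gaussian kernel (bandwidth in log10 units),
#' evaluates it at the grid bin centers, converts to bin masses by
#' multiplying by the bin area, and renormalizes so the grid sums to 1.
#' Kernel mass falling outside the grid range is recovered by the final
#' renormalization; no boundary correction is applied. Pairs outside the
#' range still contribute whatever kernel mass reaches in-range centers.
#'
#' @param pairs `data.frame` with `k`, `k_plus_1` in ms (from
#'   [select_pairs()]); all values must be > 0.
#' @param config A [jid_config()].
#' @return Object of class `jid`: list with `masses` (n_bins x n_bins
#'   matrix, rows = k bin ascending, columns = k+1 bin ascending),
#'   `bin_edges_log10`, `bin_centers_log10`, `n_pairs_used`, `variant`,
#'   `config`.
#' @export
compute_jid <- function(pairs, config = jid_config()) {
  stopifnot(inherits(config, "jid_config"))
  if (nrow(pairs) == 0L) {
    stop("cannot build a JID from zero interval pairs", call. = FALSE)
  }
  if (any(pairs$k <= 0) || any(pairs$k_plus_1 <= 0)) {
    stop("all intervals must be > 0 ms", call. = FALSE)
  }
  b <- jid_bins(config)
  h <- config$bandwidth
  # aggregate duplicate pairs into multiplicities: mathematically a
  # no-op, and it makes the grid exactly invariant to duplicating the
  # whole pair set (the renormalization cancels the doubled weights
  # bit for bit)
  key <- paste(pairs$k, pairs$k_plus_1)
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  lx <- log10(pairs$k[first])
  ly <- log10(pairs$k_plus_1[first])
  # separable Gaussian kernel: density at center (cx, cy) is
  # mean_i phi((cx - lx_i)/h) phi((cy - ly_i)/h) / h^2,
  # so the grid is a cross-product of per-dimension kernel matrices.
  Kx <- dnorm(outer(lx, b$centers, "-") / h) / h
  Ky <- dnorm(outer(ly, b$centers, "-") / h) / h
  dens <- crossprod(Kx * w, Ky) / nrow(pairs)
  area <- diff(b$edges)[1]^2
  masses <- dens * area
  tot <- sum(masses)
  if (tot <= 0) {
    stop("all kernel mass fell outside the grid range", call. = FALSE)
  }
  masses <- masses / tot
  structure(list(masses = masses,
                 bin_edges_log10 = b$edges,
                 bin_centers_log10 = b$centers,
                 n_pairs_used = nrow(pairs),
                 variant = config$variant,
                 config = config),
            class = "jid")
}

#' @export
print.jid <- function(x, ...) {
  cat(sprintf("JID (%s): %d x %d bins over log10 ms [%g, %g], %d pairs\n",
              x$variant, nrow(x$masses), ncol(x$masses),
              x$bin_edges_log10[1],
              x$bin_edges_log10[length(x$bin_edges_log10)],
              x$n_pairs_used))
  invisible(x)
}

#' Ravel a JID grid to the feature vector used by the regressions
#'
#' Column-major raveling with the k-bin index varying fastest, giving the
#' 2500-long feature vector for the default grid.
#'
#' @param jid A `jid` object.
#' @return Numeric vector of length `n_bins^2`.
#' @export
jid_vector <- function(jid) {
  as.vector(jid$masses)
}

#' Shannon entropy of a JID in bits
#'
#' `H = -sum p_i log2 p_i` over bins with positive mass. The grid must be
#' normalized (sum 1 within 1e-9).
#'
#' @param jid A `jid` object or a nonnegative mass matrix.
#' @return Entropy in bits, between 0 and `2 log2(n_bins)`.
#' @export
jid_entropy <- function(jid) {
  m <- if (inherits(jid, "jid")) jid$masses else jid
  if (abs(sum(m) - 1) > 1e-9) {
    stop("JID grid is not normalized (sum != 1)", call. = FALSE)
  }
  p <- m[m > 0]
  -sum(p * log2(p))
}

#' Median daily smartphone usage (log10 count)
#'
#' Counts touches per 24-h calendar day (UTC by default), excludes days
#' with no touches, and returns the log10 of the median daily count.
#'
#' @param events Event table for one participant.
#' @param tz_offset_ms Offset added to timestamps before day binning
#'   (default 0 = UTC midnight boundaries).
#' @return log10 median daily touch count.
#' @export
usage_per_day <- function(events, tz_offset_ms = 0) {
  if (nrow(events) == 0L) {
    stop("no events: usage undefined", call. = FALSE)
  }
  day <- floor((events$timestamp_ms + tz_offset_ms) / 86400000)
  counts <- as.numeric(table(day))  # zero-touch days never appear
  log10(median(counts))
}

#' Write a JID grid as CSV plus a JSON sidecar
#'
#' The CSV holds the 50 x 50 masses (row = k bin ascending, column =
#' k+1 bin ascending); the sidecar records bin edges, bandwidth, number
#' of pairs and variant so the artifact is self-describing.
#'
#' @param jid A `jid` object.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_jid <- function(jid, path) {
  write.table(jid$masses, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  meta <- list(bin_edges_log10 = jid$bin_edges_log10,
               bandwidth = jid$config$bandwidth,
               n_pairs_used = jid$n_pairs_used,
               variant = jid$variant)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a JID grid written by [write_jid()]
#' @param path CSV path used in [write_jid()].
#' @return A `jid` object (config reconstructed from the sidecar).
#' @export
read_jid <- function(path) {
  masses <- as.matrix(read.csv(path, header = FALSE))
  dimnames(masses) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- nrow(masses)
  cfg <- jid_config(n_bins = n,
                    log10_range_ms = range(meta$bin_edges_log10),
                    bandwidth = meta$bandwidth,
                    variant = meta$variant)
  b <- jid_bins(cfg)
  structure(list(masses = masses,
                 bin_edges_log10 = b$edges,
                 bin_centers_log10 = b$centers,
                 n_pairs_used = meta$n_pairs_used,
                 variant = meta$variant,
                 config = cfg),
            class = "jid")
}
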