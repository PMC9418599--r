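#' Build the log-transformed response matrix from a set of JIDs
#'
#' Stacks the raveled JID grids into a participants x bins matrix,
#' replaces every zero mass by the minimum positive mass encountered
#' anywhere in the population, and log10-transforms.
#'
#' @param jids List of `jid` objects sharing one configuration.
#' @return Numeric matrix (participants x n_bins^2) of log10 masses.
#'   Attributes: `zero_replacement` (the substituted mass),
#'   `participant_ids` when the list is named, `grid_dim`.
#' @export
build_response <- function(jids) {
  stopifnot(length(jids) >= 1L)
  nb <- vapply(jids, function(j) nrow(j$masses), integer(1))
  if (length(unique(nb)) != 1L) {
    stop("all JIDs must share one grid configuration", call. = FALSE)
  }
  Y <- do.call(rbind, lapply(jids, jid_vector))
  pos <- Y[Y > 0]
  if (length(pos) == 0L) {
    stop("no positive mass anywhere in the population", call. = FALSE)
  }
  repl <- min(pos)
  if (any(colSums(Y > 0) == 0L)) {
    warning("some bins carry zero mass across the whole cohort; ",
            "replaced by the population minimum everywhere",
            call. = FALSE)
  }
  Y[Y == 0] <- repl
  Y <- log10(Y)
  attr(Y, "zero_replacement") <- repl
  if (!is.null(names(jids))) attr(Y, "participant_ids") <- names(jids)
  attr(Y, "grid_dim") <- c(nb[1], nb[1])
  Y
}

check_design <- function(X, n_y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != n_y) stop("nrow(X) must match the response", call. = FALSE)
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  Xi <- cbind(`(intercept)` = 1, X)
  if (nrow(Xi) <= ncol(Xi)) {
    stop("too few rows for the number of predictors (no residual dof)",
         call. = FALSE)
  }
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):ncol(Xi)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Xi
}

#' Robust regression of one response on a design matrix
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685), residual scale re-estimated each iteration by
#' the median absolute residual / 0.6745, at most `max_iter` iterations,
#' convergence at `tol` relative change in coefficients. Coefficient
#' standard errors come from the final weighted least-squares step;
#' model R-squared and the F statistic against the intercept-only model
#' are computed from the unweighted residuals at the robust coefficients.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (numeric, no intercept column; one is added).
#' @param tune Bisquare tuning constant (default 4.685).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @return List with `beta`, `se`, `t`, `p` (named, intercept first),
#'   `r2`, `f`, `df_resid`, `iterations`.
#' @export
fit_bin <- function(y, X, tune = 4.685, max_iter = 50, tol = 1e-8) {
  Xi <- check_design(X, length(y))
  fit <- cpp_irls_matrix(Xi, as.matrix(as.numeric(y)), tune, max_iter, tol)
  nm <- colnames(Xi)
  list(beta = setNames(fit$beta[, 1], nm),
       se = setNames(fit$se[, 1], nm),
       t = setNames(fit$t[, 1], nm),
       p = setNames(fit$p[, 1], nm),
       r2 = fit$r2[1], f = fit$f[1],
       df_resid = fit$df_resid, iterations = fit$iterations[1])
}

#' Scalar-outcome robust regression
#'
#' Convenience wrapper around [fit_bin()] for per-participant scalar
#' outcomes (usage, entropy, preference scales).
#'
#' @inheritParams fit_bin
#' @return See [fit_bin()].
#' @export
scalar_robust_regression <- function(y, X, tune = 4.685, max_iter = 50,
                                     tol = 1e-8) {
  fit_bin(y, X, tune = tune, max_iter = max_iter, tol = tol)
}

#' Mass univariate robust regression over all JID bins
#'
#' Fits [fit_bin()] independently to every column of the response matrix
#' and assembles the per-bin statistics as grid maps.
#'
#' @param Y Response matrix from [build_response()] (participants x
#'   bins).
#' @param X Design matrix (no intercept column).
#' @param grid_dim Grid dimensions; defaults to the `grid_dim` attribute
#'   of `Y` or a square grid.
#' @inheritParams fit_bin
#' @return Object of class `bin_stats`: list with `beta`, `se`, `t`, `p`
#'   (coefficient x bin matrices, intercept first), `r2`, `f` (per-bin
#'   vectors), `predictors`, `grid_dim`, `df_resid`, `n`.
#' @export
mass_univariate <- function(Y, X, grid_dim = NULL, tune = 4.685,
                            max_iter = 50, tol = 1e-8) {
  Y <- as.matrix(Y)
  Xi <- check_design(X, nrow(Y))
  if (is.null(grid_dim)) {
    grid_dim <- attr(Y, "grid_dim")
    if (is.null(grid_dim)) {
      side <- sqrt(ncol(Y))
      if (side != round(side)) {
        stop("ncol(Y) is not square; supply grid_dim", call. = FALSE)
      }
      grid_dim <- c(side, side)
    }
  }
  fit <- cpp_irls_matrix(Xi, Y, tune, max_iter, tol)
  rownames(fit$beta) <- rownames(fit$se) <- rownames(fit$t) <-
    rownames(fit$p) <- colnames(Xi)
  structure(list(beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
                 r2 = fit$r2, f = fit$f,
                 predictors = colnames(Xi),
                 grid_dim = as.integer(grid_dim),
                 df_resid = fit$df_resid, n = nrow(Y)),
            class = "bin_stats")
}

#' Extract one per-bin statistic as a grid map
#'
#' @param stats A `bin_stats` object.
#' @param what One of `"beta"`, `"t"`, `"p"`, `"se"` (requires
#'   `predictor`) or `"r2"`, `"f"`.
#' @param predictor Coefficient name for coefficient-level maps.
#' @return Matrix of dimension `grid_dim` (rows = k bin, columns = k+1
#'   bin).
#' @export
stats_map <- function(stats, what = "t", predictor = NULL) {
  stopifnot(inherits(stats, "bin_stats"))
  v <- if (what %in% c("r2", "f")) {
    stats[[what]]
  } else {
    if (is.null(predictor)) stop("predictor required for ", what,
                                 call. = FALSE)
    stats[[what]][predictor, ]
  }
  matrix(v, nrow = stats$grid_dim[1], ncol = stats$grid_dim[2])
}

#' Two-dimensional cluster-based resampling correction
#'
#' Forms clusters of bins whose per-bin two-sided p value for the
#' predictor of interest falls below the cluster-forming threshold
#' (8-connected neighborhoods by default) and assigns each cluster the
#' sum of the squared predictor t statistics over member bins as its
#' mass (the per-regressor 1-df F). The null distribution of the maximum
#' cluster mass is built Freedman-Lane style: the fitted effect of the
#' predictor of interest is removed from the response, the reduced model
#' is refit, and each resample adds row-resampled reduced-model
#' residuals back onto the nuisance fit (one shared index vector across
#' bins, preserving the spatial correlation of the grid) before
#' refitting the full robust model and clustering as above. Rows are
#' permuted by default; `resample = "bootstrap"` draws them with
#' replacement instead, which is measurably conservative for the
#' family-wise error rate because shared duplicated rows reduce the
#' effective degrees of freedom of every bin at once. A cluster is
#' significant when its corrected p value (the fraction of null maxima
#' at or above its mass) is at most `alpha`.
#'
#' @param stats `bin_stats` from [mass_univariate()] on the same `Y`,
#'   `X`.
#' @param Y Response matrix.
#' @param X Design matrix (no intercept column).
#' @param predictor Name of the predictor of interest (a column of `X`).
#' @param n_boot Number of resamples (>= 20; the reference analysis
#'   used 1000).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param seed Required RNG seed for the resampling.
#' @param cf_alpha Cluster-forming per-bin threshold (default 0.05).
#' @param connectivity 4 or 8 (default 8).
#' @param resample `"permutation"` (default) or `"bootstrap"`.
#' @inheritParams fit_bin
#' @return Object of class `cluster_result`: list with `clusters`
#'   (data.frame: id, n_bins, mass, p_corrected, significant), `members`
#'   (list of bin-index vectors), `labels` (grid matrix of cluster ids),
#'   `sig_mask` (logical grid), `boot_max`, `threshold`, and the
#'   parameters used (including `seed`).
#' @export
cluster_correct <- function(stats, Y, X, predictor, n_boot = 1000,
                            alpha = 0.05, seed, cf_alpha = 0.05,
                            connectivity = 8, resample = "permutation",
                            tune = 4.685, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(stats, "bin_stats"))
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  if (n_boot < 20) {
    stop("n_boot < 20: bootstrap quantile would be unstable",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  Y <- as.matrix(Y)
  Xi <- check_design(X, nrow(Y))
  if (!predictor %in% colnames(Xi)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  pred_idx <- match(predictor, colnames(Xi))
  nr <- stats$grid_dim[1]; nc <- stats$grid_dim[2]

  if (!resample %in% c("permutation", "bootstrap")) {
    stop("resample must be 'permutation' or 'bootstrap'", call. = FALSE)
  }
  p_obs <- stats$p[predictor, ]
  mask <- p_obs < cf_alpha
  labels <- cpp_label_clusters(mask, nr, nc, connectivity)
  K <- max(labels)
  members <- if (K > 0) split(which(labels > 0), labels[labels > 0]) else
    list()
  t_pred <- stats$t[predictor, ]
  mass <- vapply(members, function(ix) sum(t_pred[ix]^2), numeric(1))

  # H0 response: remove the fitted effect of the predictor of interest,
  # keep the nuisance structure, and split the reduced-model refit into
  # fitted part and exchangeable residual rows
  Y0 <- Y - outer(Xi[, pred_idx], stats$beta[predictor, ])
  st0 <- cpp_irls_matrix(Xi, Y0, tune, max_iter, tol)
  B <- Xi %*% st0$beta
  R <- Y0 - B
  set.seed(seed)
  boot_max <- cpp_cluster_bootstrap(Xi, B, R, pred_idx - 1L, n_boot,
                                    cf_alpha, nr, nc, connectivity,
                                    tune, max_iter, tol,
                                    resample == "bootstrap")
  threshold <- quantile(boot_max, 1 - alpha, type = 1, names = FALSE)
  p_corr <- vapply(mass, function(m) mean(boot_max >= m), numeric(1))
  # p_corr <= alpha agrees with the mass > threshold rule up to ties and
  # remains well defined at the alpha = 1 endpoint
  significant <- p_corr <= alpha
  sig_mask <- matrix(FALSE, nr, nc)
  for (k in which(significant)) sig_mask[members[[k]]] <- TRUE
  structure(list(
    clusters = data.frame(id = seq_along(members),
                          n_bins = lengths(members),
                          mass = unname(mass),
                          p_corrected = unname(p_corr),
                          significant = unname(significant)),
    members = members,
    labels = matrix(labels, nr, nc),
    sig_mask = sig_mask,
    boot_max = boot_max,
    threshold = threshold,
    predictor = predictor, n_boot = n_boot, alpha = alpha,
    cf_alpha = cf_alpha, connectivity = connectivity,
    resample = resample, seed = seed),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "2-D cluster correction: %d cluster(s), %d significant at alpha %g (%d resamples, seed %s)\n",
    nrow(x$clusters), sum(x$clusters$significant), x$alpha, x$n_boot,
    format(x$seed)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate mask
#'
#' Step-up FDR control: returns which p values are rejected at level
#' `alpha`.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical vector, `TRUE` = rejected.
#' @export
fdr_correct <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") <= alpha
}
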