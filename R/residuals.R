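#' Two-step residualization of significant JID bins
#'
#' For every bin in the cluster-corrected significance mask: step one
#' regresses the bin response on gender (ordinary least squares with
#' intercept) and keeps the residuals; step two regresses those on age
#' and keeps the residuals together with the sign of the age slope. The
#' residuals express each participant's displacement from the cohort age
#' trend at that bin — displacement in the direction of the trend is
#' read as accelerated aging, against it as decelerated.
#'
#' @param Y Response matrix from [build_response()].
#' @param gender Numeric gender code per participant (1 = male,
#'   2 = female).
#' @param age Age in years per participant.
#' @param sig_mask Logical grid (or vector) selecting the bins, normally
#'   `cluster_result$sig_mask`.
#' @return Object of class `residual_matrix`: list with `residuals`
#'   (participants x bins), `slope` and `slope_sign` per bin, and `bins`
#'   (data.frame `row`, `col`, `index` in grid raveling order). Empty
#'   mask gives zero-column results.
#' @export
two_step_residuals <- function(Y, gender, age, sig_mask) {
  Y <- as.matrix(Y)
  stopifnot(length(gender) == nrow(Y), length(age) == nrow(Y))
  grid_dim <- if (is.matrix(sig_mask)) dim(sig_mask) else {
    gd <- attr(Y, "grid_dim")
    if (is.null(gd)) c(ncol(Y), 1L) else gd
  }
  idx <- which(as.vector(sig_mask))
  bins <- data.frame(row = (idx - 1L) %% grid_dim[1] + 1L,
                     col = (idx - 1L) %/% grid_dim[1] + 1L,
                     index = idx)
  if (length(idx) == 0L) {
    return(structure(list(residuals = matrix(numeric(0), nrow(Y), 0),
                          slope = numeric(0), slope_sign = integer(0),
                          bins = bins, age = age),
                     class = "residual_matrix"))
  }
  Ysub <- Y[, idx, drop = FALSE]
  r1 <- lm.fit(cbind(1, gender), Ysub)$residuals
  fit2 <- lm.fit(cbind(1, age), r1)
  slope <- fit2$coefficients[2, ]
  structure(list(residuals = fit2$residuals,
                 slope = unname(slope),
                 slope_sign = sign(unname(slope)),
                 bins = bins, age = age),
            class = "residual_matrix")
}

chebyshev_dist <- function(r1, c1, r2, c2) pmax(abs(r1 - r2), abs(c1 - c2))
euclid_dist <- function(r1, c1, r2, c2) sqrt((r1 - r2)^2 + (c1 - c2)^2)

#' Classify residual pairs as consistent or inconsistent aging
#'
#' Correlates the second-step (age) residuals of every pair of
#' significant bins separated by more than `min_dist` bins (Chebyshev
#' distance by default). Pairs passing Benjamini-Hochberg FDR at `alpha`
#' and exceeding `r2_min` are labelled: `consistent` when individuals
#' displaced toward accelerated aging in one bin are also accelerated in
#' the other, i.e. `sign(cor) * sign(slope_i) * sign(slope_j) = +1`;
#' `inconsistent` when the triple product is negative.
#'
#' @param res A `residual_matrix` from [two_step_residuals()].
#' @param min_dist Pairs must be farther apart than this (default 5).
#' @param r2_min Minimum correlation R-squared to retain (default 0.1).
#' @param alpha FDR level over all distance-qualifying pairs
#'   (default 0.001).
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return `data.frame` with one row per distance-qualifying pair:
#'   bin coordinates, `distance`, `r`, `r2`, `p`, `fdr_pass`, `retained`
#'   and `label` (`NA` for pairs not retained).
#' @export
classify_pairs <- function(res, min_dist = 5, r2_min = 0.1,
                           alpha = 0.001, metric = "chebyshev") {
  stopifnot(inherits(res, "residual_matrix"))
  k <- ncol(res$residuals)
  empty <- data.frame(bin_i_row = integer(0), bin_i_col = integer(0),
                      bin_j_row = integer(0), bin_j_col = integer(0),
                      distance = numeric(0), r = numeric(0),
                      r2 = numeric(0), p = numeric(0),
                      fdr_pass = logical(0), retained = logical(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (k < 2L) return(empty)
  distfun <- switch(metric, chebyshev = chebyshev_dist,
                    euclidean = euclid_dist,
                    stop("unknown distance metric: ", metric,
                         call. = FALSE))
  b <- res$bins
  ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  d <- distfun(b$row[ij[, 1]], b$col[ij[, 1]],
               b$row[ij[, 2]], b$col[ij[, 2]])
  keep <- d > min_dist
  if (!any(keep)) return(empty)
  ij <- ij[keep, , drop = FALSE]
  d <- d[keep]
  C <- cor(res$residuals)
  r <- C[ij]
  n <- nrow(res$residuals)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), n - 2)
  fdr_pass <- fdr_correct(p, alpha)
  retained <- fdr_pass & r^2 > r2_min
  triple <- sign(r) * res$slope_sign[ij[, 1]] * res$slope_sign[ij[, 2]]
  label <- ifelse(retained,
                  ifelse(triple > 0, "consistent", "inconsistent"),
                  NA_character_)
  out <- data.frame(bin_i_row = b$row[ij[, 1]], bin_i_col = b$col[ij[, 1]],
                    bin_j_row = b$row[ij[, 2]], bin_j_col = b$col[ij[, 2]],
                    distance = d, r = r, r2 = r^2, p = p,
                    fdr_pass = fdr_pass, retained = retained,
                    label = label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-bin maximum pair R-squared maps by label
#'
#' Summarizes a pair classification as two grid maps: for each bin, the
#' largest R-squared over its retained consistent (respectively
#' inconsistent) pairs.
#'
#' @param pairs Output of [classify_pairs()].
#' @param grid_dim Grid dimensions, e.g. `c(50, 50)`.
#' @return List of two matrices, `consistent` and `inconsistent`
#'   (0 where a bin has no retained pair of that label).
#' @export
pair_r2_maps <- function(pairs, grid_dim = c(50L, 50L)) {
  maps <- list(consistent = matrix(0, grid_dim[1], grid_dim[2]),
               inconsistent = matrix(0, grid_dim[1], grid_dim[2]))
  for (lab in names(maps)) {
    sel <- pairs$retained & !is.na(pairs$label) & pairs$label == lab
    for (i in which(sel)) {
      for (end in c("i", "j")) {
        r <- pairs[[paste0("bin_", end, "_row")]][i]
        c <- pairs[[paste0("bin_", end, "_col")]][i]
        maps[[lab]][r, c] <- max(maps[[lab]][r, c], pairs$r2[i])
      }
    }
  }
  maps
}
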