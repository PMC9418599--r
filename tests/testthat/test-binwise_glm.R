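test_that("response building replaces zeros by the population minimum", {
  mk_jid <- function(m) {
    structure(list(masses = m, variant = "full"), class = "jid")
  }
  m1 <- matrix(c(0.1, 0, 0.01, 0.89), 2, 2)
  m2 <- matrix(c(0.001, 0.4, 0.4, 0.199), 2, 2)
  Y <- build_response(list(a = mk_jid(m1), b = mk_jid(m2)))
  expect_equal(Y[1, 1:3], c(-1, -3, -2), ignore_attr = TRUE)
  expect_equal(attr(Y, "zero_replacement"), 0.001)
  # no zeros anywhere -> plain log10
  Y2 <- build_response(list(a = mk_jid(m2)))
  expect_equal(Y2[1, ], log10(as.vector(m2)), ignore_attr = TRUE)
  # an all-zero bin across the cohort warns
  m3 <- m1; m3[2, 1] <- 0
  m4 <- m2; m4[2, 1] <- 0
  expect_warning(build_response(list(mk_jid(m3), mk_jid(m4))), "zero mass")
})

test_that("robust fit: exact recovery, constants, rank errors", {
  set.seed(5)
  A <- rnorm(50)
  D <- rep(c(1, 2), 25)
  f <- fit_bin(2 * A + 1, cbind(A = A, D = D))
  expect_equal(unname(f$beta["A"]), 2, tolerance = 1e-9)
  expect_equal(f$r2, 1)
  # y = D exactly
  fd <- fit_bin(D, cbind(A = A, D = D))
  expect_equal(unname(fd$beta["D"]), 1, tolerance = 1e-9)
  expect_equal(unname(fd$beta["A"]), 0, tolerance = 1e-9)
  # constant response
  fc <- fit_bin(rep(3, 50), cbind(A = A, D = D))
  expect_equal(unname(fc$beta[-1]), c(0, 0), tolerance = 1e-12)
  expect_equal(fc$r2, 0)
  # collinear columns named
  expect_error(fit_bin(rnorm(50), cbind(A = A, B = A)), "collinear")
  # too few rows for dof
  expect_error(fit_bin(rnorm(3), cbind(a = rnorm(3), b = rnorm(3),
                                       c = rnorm(3))), "rows")
})

test_that("IRLS equals OLS when downweighting is off and resists outliers", {
  set.seed(6)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n)
  ols <- oracle_ols(y, X)
  f <- fit_bin(y, X, tune = 1e8)
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-8)
  # converged bisquare coefficients are a fixed point of the R oracle step
  fr <- fit_bin(y, X)
  step <- oracle_irls_step(y, X, fr$beta)
  expect_lt(max(abs(step - fr$beta) / pmax(abs(step), 1)), 1e-6)
  # bounded influence: one gross outlier moves IRLS less than OLS
  y2 <- y; y2[1] <- y[1] + 1000
  d_irls <- max(abs(fit_bin(y2, X)$beta - fr$beta))
  d_ols <- max(abs(oracle_ols(y2, X) - ols))
  expect_lt(d_irls, d_ols / 10)
})

test_that("equivariance: shifting and scaling the response", {
  set.seed(8)
  n <- 80
  X <- cbind(a = rnorm(n), d = sample(1:2, n, TRUE))
  y <- 0.5 * X[, 1] + rnorm(n)
  f <- fit_bin(y, X)
  fs <- fit_bin(100 * y, X)
  expect_equal(unname(fs$beta), unname(100 * f$beta), tolerance = 1e-6)
  expect_equal(fs$t, f$t, tolerance = 1e-6)
  expect_equal(fs$r2, f$r2, tolerance = 1e-9)
  fo <- fit_bin(y + 7, X)
  expect_equal(unname(fo$beta[-1]), unname(f$beta[-1]), tolerance = 1e-6)
  expect_equal(unname(fo$beta[1] - f$beta[1]), 7, tolerance = 1e-6)
})

test_that("mass univariate maps recover a planted block effect", {
  set.seed(9)
  n <- 80
  age <- runif(n, 16, 86)
  gender <- sample(1:2, n, TRUE)
  Y <- matrix(rnorm(n * 2500), n, 2500)
  # negative age effect in a 5x5 fast-fast block (rows/cols 10..14)
  block <- as.vector(outer(10:14, (10:14 - 1) * 50, "+"))
  Y[, block] <- Y[, block] - 0.05 * (age - 50)
  st <- mass_univariate(Y, cbind(age = age, gender = gender))
  tmap <- stats_map(st, "t", "age")
  expect_true(all(tmap[10:14, 10:14] < 0))
  expect_true(which.max(abs(tmap)) %in% block)
  # R2/t/p consistency: p from t at the model dof
  expect_equal(st$p["age", 1],
               2 * pt(-abs(st$t["age", 1]), st$df_resid),
               tolerance = 1e-10)
  # permuted ages: max |t| consistent with the null distribution
  st0 <- mass_univariate(Y[, -block], cbind(age = sample(age),
                                            gender = gender),
                         grid_dim = c(50, 49))
  expect_lt(mean(abs(st0$t["age", ]) > 1.96), 0.10)
})

test_that("cluster correction finds planted clusters, not isolated spikes", {
  set.seed(10)
  n <- 60
  age <- runif(n, 16, 86)
  gender <- sample(1:2, n, TRUE)
  Y <- matrix(rnorm(n * 2500), n, 2500)
  block <- as.vector(outer(20:27, (20:27 - 1) * 50, "+"))
  Y[, block] <- Y[, block] + 0.06 * (age - 50)
  X <- cbind(age = age, gender = gender)
  st <- mass_univariate(Y, X)
  cl <- cluster_correct(st, Y, X, "age", n_boot = 200, alpha = 0.05,
                        seed = 42)
  # the planted 8x8 block is recovered as a significant cluster
  expect_true(any(cl$clusters$significant))
  expect_true(all(cl$sig_mask[20:27, 20:27]))
  # significant bins overlap the planted block well
  planted <- matrix(FALSE, 50, 50); planted[20:27, 20:27] <- TRUE
  jac <- sum(cl$sig_mask & planted) / sum(cl$sig_mask | planted)
  expect_gt(jac, 0.5)
  # determinism given the seed
  cl2 <- cluster_correct(st, Y, X, "age", n_boot = 200, alpha = 0.05,
                         seed = 42)
  expect_identical(cl$boot_max, cl2$boot_max)
  expect_identical(cl$clusters, cl2$clusters)
  # guards
  expect_error(cluster_correct(st, Y, X, "age", n_boot = 10, seed = 1),
               "n_boot")
  expect_error(cluster_correct(st, Y, X, "age", n_boot = 100),
               "seed")
  # alpha = 1: every supra-threshold cluster significant
  cl3 <- cluster_correct(st, Y, X, "age", n_boot = 50, alpha = 1,
                         seed = 3)
  expect_true(all(cl3$clusters$significant))
  # no significant cluster has mass below a single supra-threshold bin
  tsq <- st$t["age", ]^2
  expect_true(all(cl$clusters$mass[cl$clusters$significant] >
                    min(tsq[as.vector(cl$labels) > 0])))
})

test_that("scalar robust regression recovers planted signs", {
  set.seed(12)
  hits <- replicate(100, {
    n <- 60
    age <- runif(n, 16, 86)
    gender <- sample(1:2, n, TRUE)
    # planted |effect|/sigma = 0.5 per sd(age)
    y <- -0.5 * scale(age)[, 1] + rnorm(n)
    f <- scalar_robust_regression(y, cbind(age = age, gender = gender))
    unname(f$beta["age"]) < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Benjamini-Hochberg mask matches hand computation", {
  expect_equal(fdr_correct(c(1e-4, 0.5, 0.9), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(fdr_correct(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_length(fdr_correct(numeric(0), 0.05), 0L)
  # step-up: a borderline p rescued by a smaller one
  p <- c(0.01, 0.04, 0.9)
  expect_equal(fdr_correct(p, 0.06), c(TRUE, TRUE, FALSE))
})

test_that("extended model supports seven predictors with R2 nesting", {
  set.seed(13)
  n <- 100
  X <- cbind(A = runif(n, 16, 86), U = rnorm(n, 2.5, 0.3),
             T = runif(n), Y = runif(n, 1, 25), Q = runif(n),
             S = rnorm(n, 5.8, 0.6), D = sample(1:2, n, TRUE))
  y <- 0.01 * X[, "A"] - 0.2 * X[, "U"] + 0.1 * X[, "D"] + rnorm(n)
  # on the OLS fit (downweighting off) R2 never decreases as columns
  # are added
  r2 <- vapply(seq_len(ncol(X)), function(k) {
    fit_bin(y, X[, seq_len(k), drop = FALSE], tune = 1e9)$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # full robust fit returns one coefficient per predictor + intercept
  f <- fit_bin(y, X)
  expect_length(f$beta, 8L)
  expect_true(all(is.finite(f$t)))
})
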