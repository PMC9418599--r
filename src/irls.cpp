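#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Small dense Cholesky solve: A (p x p, column-major, symmetric positive
// definite) b (length p). Overwrites nothing; returns false on failure.
static bool chol_solve(const double *A, const double *b, double *x, int p,
                       std::vector<double> &L) {
  // L lower-triangular, column-major
  for (int j = 0; j < p; ++j) {
    double d = A[j + j * p];
    for (int k = 0; k < j; ++k) d -= L[j + k * p] * L[j + k * p];
    if (d <= 1e-300) return false;
    d = std::sqrt(d);
    L[j + j * p] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i + j * p];
      for (int k = 0; k < j; ++k) s -= L[i + k * p] * L[j + k * p];
      L[i + j * p] = s / d;
    }
  }
  // forward solve L z = b (reuse x as z)
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i + k * p] * x[k];
    x[i] = s / L[i + i * p];
  }
  // back solve L' x = z
  for (int i = p - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < p; ++k) s -= L[k + i * p] * x[k];
    x[i] = s / L[i + i * p];
  }
  return true;
}

// Invert SPD matrix via Cholesky; returns diagonal of inverse in dinv.
static bool chol_inv_diag(const double *A, double *dinv, int p,
                          std::vector<double> &L, std::vector<double> &col) {
  std::vector<double> e(p), x(p);
  for (int j = 0; j < p; ++j) {
    std::fill(e.begin(), e.end(), 0.0);
    e[j] = 1.0;
    if (!chol_solve(A, e.data(), x.data(), p, L)) return false;
    dinv[j] = x[j];
  }
  (void)col;
  return true;
}

struct IRLSWork {
  std::vector<double> beta, beta_new, r, w, absr, tmp, xtwx, xtwy, L, dinv;
  double inv_c = 0.0;
  bool use_r_weights = false;  // weights implied by r and inv_c
  IRLSWork(int n, int p)
      : beta(p), beta_new(p), r(n), w(n), absr(n), tmp(n), xtwx(p * p),
        xtwy(p), L(p * p), dinv(p) {}
};

// Diagonal of (X'X)^{-1}; shared across response columns for the
// M-estimator covariance.
static std::vector<double> xtx_inv_diag(const double *X, int n, int p) {
  std::vector<double> xtx(p * p, 0.0), L(p * p, 0.0), dinv(p), col(p);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < p; ++a)
      for (int b = a; b < p; ++b)
        xtx[a + b * p] += X[i + a * n] * X[i + b * n];
  for (int a = 0; a < p; ++a)
    for (int b = 0; b < a; ++b) xtx[a + b * p] = xtx[b + a * p];
  if (!chol_inv_diag(xtx.data(), dinv.data(), p, L, col))
    stop("singular design matrix");
  return dinv;
}

static double median_abs(std::vector<double> &tmp, int n) {
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
  double med = tmp[n / 2];
  if (n % 2 == 0) {
    double lo = *std::max_element(tmp.begin(), tmp.begin() + n / 2);
    med = 0.5 * (med + lo);
  }
  return med;
}

// One robust fit (Tukey bisquare IRLS, MAD scale) of y on X.
// X: n x p column-major (first column should be the intercept).
// Outputs written into beta (p), se (p), tval (p), pval (p);
// returns via refs: r2, fstat, iterations.
static void irls_one(const double *X, const double *y, int n, int p,
                     double tune, int max_iter, double tol, IRLSWork &wk,
                     const double *xtx_dinv, double *beta, double *se,
                     double *tval, double *pval, double &r2, double &fstat,
                     int &iters, int pred_only = -1) {
  // OLS start: weights all 1
  std::fill(wk.w.begin(), wk.w.end(), 1.0);
  wk.use_r_weights = false;
  iters = 0;
  bool have_fit = false;
  // Aitken extrapolation state: IRLS converges linearly, so an
  // occasional geometric-series jump roughly halves the iteration count
  // without moving the fixed point (convergence is only ever declared
  // on an ordinary step).
  bool have_prev_step = false;
  double prev_step_norm = 0.0;
  for (int it = 0; it <= max_iter; ++it) {
    // weighted normal equations
    std::fill(wk.xtwx.begin(), wk.xtwx.end(), 0.0);
    std::fill(wk.xtwy.begin(), wk.xtwy.end(), 0.0);
    if (p == 3 && X[0] == 1.0 && X[n - 1] == 1.0) {
      // common case: intercept + two predictors
      const double *x1 = X + n, *x2 = X + 2 * n;
      double s0 = 0, s1 = 0, s2 = 0, s11 = 0, s12 = 0, s22 = 0;
      double sy = 0, s1y = 0, s2y = 0;
      const bool rw = wk.use_r_weights;
      const double inv_c = wk.inv_c;
      for (int i = 0; i < n; ++i) {
        double wi;
        if (rw) {
          double u = wk.r[i] * inv_c;
          double q = 1.0 - u * u;
          q = q > 0.0 ? q : 0.0;
          wi = q * q;
          wk.w[i] = wi;
        } else {
          wi = wk.w[i];
        }
        double w1 = wi * x1[i], w2 = wi * x2[i], wy = wi * y[i];
        s0 += wi; s1 += w1; s2 += w2;
        s11 += w1 * x1[i]; s12 += w1 * x2[i]; s22 += w2 * x2[i];
        sy += wy; s1y += w1 * y[i]; s2y += w2 * y[i];
      }
      wk.xtwx[0] = s0; wk.xtwx[1] = s1; wk.xtwx[2] = s2;
      wk.xtwx[3] = s1; wk.xtwx[4] = s11; wk.xtwx[5] = s12;
      wk.xtwx[6] = s2; wk.xtwx[7] = s12; wk.xtwx[8] = s22;
      wk.xtwy[0] = sy; wk.xtwy[1] = s1y; wk.xtwy[2] = s2y;
    } else {
      if (wk.use_r_weights) {
        for (int i = 0; i < n; ++i) {
          double u = wk.r[i] * wk.inv_c;
          double q = 1.0 - u * u;
          q = q > 0.0 ? q : 0.0;
          wk.w[i] = q * q;
        }
      }
      for (int i = 0; i < n; ++i) {
        double wi = wk.w[i];
        if (wi == 0.0) continue;
        for (int a = 0; a < p; ++a) {
          double xa = X[i + a * n] * wi;
          wk.xtwy[a] += xa * y[i];
          for (int b = a; b < p; ++b)
            wk.xtwx[a + b * p] += xa * X[i + b * n];
        }
      }
      for (int a = 0; a < p; ++a)
        for (int b = 0; b < a; ++b) wk.xtwx[a + b * p] = wk.xtwx[b + a * p];
    }
    if (!chol_solve(wk.xtwx.data(), wk.xtwy.data(), wk.beta_new.data(), p,
                    wk.L)) {
      // singular weighted system: stop with last good estimate
      if (!have_fit) stop("singular design matrix in robust fit");
      break;
    }
    if (have_fit) {
      double diff = 0.0, scale = 1.0;
      for (int a = 0; a < p; ++a) {
        diff = std::max(diff, std::fabs(wk.beta_new[a] - wk.beta[a]));
        scale = std::max(scale, std::fabs(wk.beta_new[a]));
      }
      if (diff < tol * scale) {
        std::copy(wk.beta_new.begin(), wk.beta_new.end(), wk.beta.begin());
        break;
      }
      if (have_prev_step && prev_step_norm > 0.0) {
        double lambda = diff / prev_step_norm;
        if (lambda > 0.02 && lambda < 0.95) {
          double fac = lambda / (1.0 - lambda);
          for (int a = 0; a < p; ++a)
            wk.beta_new[a] += (wk.beta_new[a] - wk.beta[a]) * fac;
        }
      }
      std::copy(wk.beta_new.begin(), wk.beta_new.end(), wk.beta.begin());
      have_prev_step = true;
      prev_step_norm = diff;
    } else {
      std::copy(wk.beta_new.begin(), wk.beta_new.end(), wk.beta.begin());
      have_fit = true;
    }
    iters = it;
    if (it == max_iter) break;
    // residuals and MAD scale
    for (int i = 0; i < n; ++i) {
      double fit = 0.0;
      for (int a = 0; a < p; ++a) fit += X[i + a * n] * wk.beta[a];
      wk.r[i] = y[i] - fit;
      wk.absr[i] = std::fabs(wk.r[i]);
    }
    std::copy(wk.absr.begin(), wk.absr.end(), wk.tmp.begin());
    double s = median_abs(wk.tmp, n) / 0.6745;
    if (s < 1e-12) break;  // (near-)perfect fit
    double inv_c = 1.0 / (tune * s);
    wk.inv_c = inv_c;
    wk.use_r_weights = true;
  }
  std::copy(wk.beta.begin(), wk.beta.end(), beta);

  // final residuals (unweighted) at robust coefficients; the r2/F
  // bookkeeping is skipped in the resampling hot path (pred_only >= 0),
  // where only the predictor t is consumed
  double ss_res = 0.0, ybar = 0.0, ss_tot = 0.0;
  bool want_r2 = pred_only < 0;
  if (want_r2) {
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
  }
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int a = 0; a < p; ++a) fit += X[i + a * n] * wk.beta[a];
    wk.r[i] = y[i] - fit;
    wk.absr[i] = std::fabs(wk.r[i]);
    ss_res += wk.r[i] * wk.r[i];
    if (want_r2) ss_tot += (y[i] - ybar) * (y[i] - ybar);
  }

  // M-estimator covariance with Huber's small-sample correction
  // (as in summary() for bisquare rlm fits):
  //   sigma2 = K^2 * [sum psi(r)^2 / (n - p)] / mean(psi'(r))^2,
  //   Cov(beta) = sigma2 * (X'X)^{-1},
  // psi the bisquare influence function at the converged MAD scale.
  int df = n - p;
  std::copy(wk.absr.begin(), wk.absr.end(), wk.tmp.begin());
  double s_fin = median_abs(wk.tmp, n) / 0.6745;
  double sigma2;
  if (s_fin < 1e-300) {
    sigma2 = df > 0 ? ss_res / df : NA_REAL;  // exact fit: OLS formula
  } else {
    double inv_c = 1.0 / (tune * s_fin);
    double sum_psi2 = 0.0, sum_dpsi = 0.0, sum_dpsi2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double u = wk.r[i] * inv_c;
      double u2 = u * u;
      double in = u2 < 1.0 ? 1.0 : 0.0;
      double q = 1.0 - u2;
      double psi = wk.r[i] * q * q * in;
      double dpsi = q * (1.0 - 5.0 * u2) * in;
      sum_psi2 += psi * psi;
      sum_dpsi += dpsi;
      sum_dpsi2 += dpsi * dpsi;
    }
    double m1 = sum_dpsi / n;
    if (m1 > 1e-12 && df > 0) {
      double var_dpsi = sum_dpsi2 / n - m1 * m1;
      double K = 1.0 + (double)p * var_dpsi / (n * m1 * m1);
      sigma2 = K * K * (sum_psi2 / df) / (m1 * m1);
    } else {
      sigma2 = df > 0 ? ss_res / df : NA_REAL;
    }
  }
  for (int a = 0; a < p; ++a) {
    if (pred_only >= 0 && a != pred_only) {
      se[a] = NA_REAL; tval[a] = NA_REAL; pval[a] = NA_REAL;
      continue;
    }
    double v = sigma2 * xtx_dinv[a];
    double s_a = (ISNAN(v) || v < 0) ? NA_REAL : std::sqrt(v);
    se[a] = s_a;
    if (ISNAN(s_a) || s_a < 1e-300) {
      tval[a] = 0.0;
      pval[a] = 1.0;
      if (std::fabs(wk.beta[a]) > 1e-10 && !ISNAN(s_a)) {
        tval[a] = wk.beta[a] > 0 ? R_PosInf : R_NegInf;
        pval[a] = 0.0;
      }
    } else {
      tval[a] = wk.beta[a] / s_a;
      // t statistic suffices in the bootstrap hot path
      pval[a] = pred_only >= 0 ? NA_REAL
                               : 2.0 * R::pt(-std::fabs(tval[a]),
                                             (double)df, 1, 0);
    }
  }
  if (!want_r2 || ss_tot < 1e-300) {
    r2 = 0.0;
    fstat = 0.0;
  } else {
    r2 = 1.0 - ss_res / ss_tot;
    if (r2 < 0.0) r2 = 0.0;
    if (r2 > 1.0) r2 = 1.0;
    double denom = (1.0 - r2) / df;
    fstat = denom < 1e-300 ? 1e12 : (r2 / (p - 1)) / denom;
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_irls_matrix(NumericMatrix X, NumericMatrix Y, double tune,
                     int max_iter, double tol) {
  int n = X.nrow(), p = X.ncol(), m = Y.ncol();
  if (Y.nrow() != n) stop("nrow(Y) must equal nrow(X)");
  NumericMatrix beta(p, m), se(p, m), tval(p, m), pval(p, m);
  NumericVector r2(m), fstat(m);
  IntegerVector iters(m);
  IRLSWork wk(n, p);
  std::vector<double> dinv = xtx_inv_diag(&X(0, 0), n, p);
  for (int j = 0; j < m; ++j) {
    double r2j, fj;
    int itj;
    irls_one(&X(0, 0), &Y(0, j), n, p, tune, max_iter, tol, wk,
             dinv.data(), &beta(0, j), &se(0, j), &tval(0, j), &pval(0, j),
             r2j, fj, itj);
    r2[j] = r2j;
    fstat[j] = fj;
    iters[j] = itj;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["t"] = tval,
                      _["p"] = pval, _["r2"] = r2, _["f"] = fstat,
                      _["df_resid"] = n - p, _["iterations"] = iters);
}

// Connected components of a boolean grid mask (column-major, nr x nc).
// connectivity 4 or 8. Writes labels (0 = background, clusters 1..K),
// returns K.
static int label_clusters(const std::vector<char> &mask, int nr, int nc,
                          int connectivity, std::vector<int> &labels,
                          std::vector<int> &stack) {
  std::fill(labels.begin(), labels.end(), 0);
  int K = 0;
  for (int start = 0; start < nr * nc; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++K;
    stack.clear();
    stack.push_back(start);
    labels[start] = K;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int r = cur % nr, c = cur / nr;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          if (connectivity == 4 && dr != 0 && dc != 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int idx = rr + cc * nr;
          if (mask[idx] && !labels[idx]) {
            labels[idx] = K;
            stack.push_back(idx);
          }
        }
      }
    }
  }
  return K;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector mask, int nr, int nc,
                                 int connectivity) {
  if (mask.size() != nr * nc) stop("mask length must be nr*nc");
  std::vector<char> m(nr * nc);
  for (int i = 0; i < nr * nc; ++i) m[i] = mask[i] == TRUE;
  std::vector<int> labels(nr * nc), stack;
  label_clusters(m, nr, nc, connectivity, labels, stack);
  IntegerVector out(nr * nc);
  std::copy(labels.begin(), labels.end(), out.begin());
  return out;
}

//' Null distribution of the maximum cluster mass (Freedman-Lane).
//'
//' X is the full design (intercept first); B the per-bin nuisance fit
//' (n x m) and R the per-bin residuals (n x m) of the full model fitted
//' to the response with the effect of the predictor of interest
//' removed. Each resample rebuilds y* = B + R[idx, ] with one shared
//' index vector (a permutation, or a with-replacement draw when
//' `replace` is true), refits the full robust model per bin, thresholds
//' the predictor t statistic at the two-sided cf_alpha critical value,
//' clusters supra-threshold bins and records the maximum cluster mass
//' (sum of squared predictor t values). Uses R's RNG.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_cluster_bootstrap(NumericMatrix X, NumericMatrix B,
                                    NumericMatrix Res, int pred, int n_boot,
                                    double cf_alpha, int nr, int nc,
                                    int connectivity, double tune,
                                    int max_iter, double tol,
                                    bool replace) {
  int n = X.nrow(), p = X.ncol(), m = B.ncol();
  if (B.nrow() != n || Res.nrow() != n || Res.ncol() != m)
    stop("B and R must be n x m");
  if (m != nr * nc) stop("ncol(B) must equal nr*nc");
  if (pred < 0 || pred >= p) stop("bad predictor index");
  NumericVector boot_max(n_boot);
  double t_crit = R::qt(1.0 - cf_alpha / 2.0, (double)(n - p), 1, 0);
  std::vector<int> idx(n);
  std::vector<double> yb(n), tvals(m);
  std::vector<char> mask(m);
  std::vector<int> labels(m), stack;
  std::vector<double> beta(p), se(p), tv(p), pv(p);
  IRLSWork wk(n, p);
  // design is fixed across resamples
  std::vector<double> Xfix(n * p);
  for (int a = 0; a < p; ++a)
    for (int i = 0; i < n; ++i) Xfix[i + a * n] = X(i, a);
  std::vector<double> dinv = xtx_inv_diag(Xfix.data(), n, p);
  for (int b = 0; b < n_boot; ++b) {
    if (replace) {
      for (int i = 0; i < n; ++i) {
        int k = (int)std::floor(unif_rand() * n);
        if (k == n) k = n - 1;
        idx[i] = k;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
        int k = (int)std::floor(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(idx[i], idx[k]);
      }
    }
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) yb[i] = B(i, j) + Res(idx[i], j);
      double r2j, fj;
      int itj;
      irls_one(Xfix.data(), yb.data(), n, p, tune, max_iter, tol, wk,
               dinv.data(), beta.data(), se.data(), tv.data(), pv.data(),
               r2j, fj, itj, pred);
      double tj = ISNAN(tv[pred]) ? 0.0 : tv[pred];
      tvals[j] = tj * tj;
      mask[j] = std::fabs(tj) > t_crit;
    }
    int K = label_clusters(mask, nr, nc, connectivity, labels, stack);
    double mx = 0.0;
    if (K > 0) {
      std::vector<double> massv(K, 0.0);
      for (int j = 0; j < m; ++j)
        if (labels[j]) massv[labels[j] - 1] += tvals[j];
      mx = *std::max_element(massv.begin(), massv.end());
    }
    boot_max[b] = mx;
  }
  return boot_max;
}
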