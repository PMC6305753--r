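#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for the penalized likelihood
//   (1/n) sum_i -l(b0, b) + sum_j MCP(|b_j|; lambda1, gamma) + lambda2 * b' Omega b
// X must be standardized: columns centered, sum of squares = n.
// The intercept is never penalized.

static inline double mcp_rho(double t, double lam1, double gamma) {
  t = std::fabs(t);
  if (t <= gamma * lam1) return lam1 * t - t * t / (2.0 * gamma);
  return 0.5 * gamma * lam1 * lam1;
}

// argmin_t (a/2) t^2 - b t + MCP(|t|; lam1, gamma); requires a > 1/gamma
static inline double mcp_update(double a, double b, double lam1, double gamma) {
  double ab = std::fabs(b);
  if (ab <= lam1) return 0.0;
  if (ab <= a * gamma * lam1) {
    double s = (b > 0) ? 1.0 : -1.0;
    return s * (ab - lam1) / (a - 1.0 / gamma);
  }
  return b / a;
}

struct WorkState {
  int n, p;
  bool has_str;
  double lam2, gamma;
  std::vector<double> u;      // Omega %*% beta
};

static double objective_gaussian(const NumericMatrix& X, const NumericVector& r,
                                 const NumericVector& beta, const WorkState& st,
                                 double lam1, const Nullable<NumericMatrix>& Omega_) {
  int n = st.n, p = st.p;
  double loss = 0.0;
  for (int i = 0; i < n; ++i) loss += r[i] * r[i];
  loss /= (2.0 * n);
  double pen = 0.0;
  for (int j = 0; j < p; ++j) pen += mcp_rho(beta[j], lam1, st.gamma);
  double quad = 0.0;
  if (st.has_str) {
    for (int j = 0; j < p; ++j) quad += beta[j] * st.u[j];
    quad *= st.lam2;
  }
  (void)X; (void)Omega_;
  return loss + pen + quad;
}

// one coordinate sweep over the index set `idx`; returns max |delta beta|
static double sweep_gaussian(const NumericMatrix& X, NumericVector& r,
                             NumericVector& beta, WorkState& st,
                             const NumericMatrix* Om, const std::vector<double>& a,
                             double lam1, const std::vector<int>& idx) {
  int n = st.n;
  double maxd = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    int j = idx[k];
    double xr = 0.0;
    const double* xj = X.begin() + (size_t)j * n;
    for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
    double b = xr / n + beta[j];
    if (st.has_str) b -= 2.0 * st.lam2 * (st.u[j] - (*Om)(j, j) * beta[j]);
    double bn = mcp_update(a[j], b, lam1, st.gamma);
    double d = bn - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      if (st.has_str) {
        const double* oj = Om->begin() + (size_t)j * st.p;
        for (int q = 0; q < st.p; ++q) st.u[q] += oj[q] * d;
      }
      beta[j] = bn;
      double ad = std::fabs(d);
      if (ad > maxd) maxd = ad;
    }
  }
  return maxd;
}

// [[Rcpp::export]]
List cd_gaussian_path(NumericMatrix X, NumericVector y,
                      Nullable<NumericMatrix> Omega, NumericVector lambda1,
                      double lambda2, double gamma,
                      double tol, int max_sweeps, bool trace) {
  int n = X.nrow(), p = X.ncol(), L = lambda1.size();
  WorkState st;
  st.n = n; st.p = p; st.gamma = gamma; st.lam2 = lambda2;
  st.has_str = (Omega.isNotNull() && lambda2 > 0);
  NumericMatrix Om_;
  const NumericMatrix* Om = NULL;
  if (st.has_str) { Om_ = NumericMatrix(Omega); Om = &Om_; }

  double b0 = mean(y);
  NumericVector r = clone(y);
  for (int i = 0; i < n; ++i) r[i] -= b0;
  NumericVector beta(p);
  st.u.assign(p, 0.0);

  std::vector<double> a(p, 1.0);
  for (int j = 0; j < p; ++j) {
    if (st.has_str) a[j] = 1.0 + 2.0 * lambda2 * (*Om)(j, j);
    if (a[j] <= 1.0 / gamma)
      stop("coordinate curvature a <= 1/gamma at OTU %d; increase gamma or lambda2", j + 1);
  }

  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;

  NumericMatrix beta_out(p, L);
  NumericVector b0_out(L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  List traces(L);

  for (int l = 0; l < L; ++l) {
    double lam1 = lambda1[l];
    int sweeps = 0;
    bool converged = false;
    std::vector<double> objtr;
    while (sweeps < max_sweeps) {
      double bmax = max(abs(beta));
      double thr = tol * std::max(1.0, bmax);
      double d_full = sweep_gaussian(X, r, beta, st, Om, a, lam1, all);
      ++sweeps;
      if (trace) objtr.push_back(objective_gaussian(X, r, beta, st, lam1, Omega));
      if (d_full < thr) { converged = true; break; }
      // active-set cycling between full sweeps
      for (int inner = 0; inner < 9 && sweeps < max_sweeps; ++inner) {
        std::vector<int> act;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
        if (act.empty()) break;
        double d = sweep_gaussian(X, r, beta, st, Om, a, lam1, act);
        ++sweeps;
        if (trace) objtr.push_back(objective_gaussian(X, r, beta, st, lam1, Omega));
        double bmax2 = max(abs(beta));
        if (d < tol * std::max(1.0, bmax2)) break;
      }
    }
    beta_out(_, l) = beta;
    b0_out[l] = b0;
    iters[l] = sweeps;
    conv[l] = converged;
    if (trace) traces[l] = wrap(objtr);
  }

  List out = List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                          _["n_iter"] = iters, _["converged"] = conv);
  if (trace) out["objective_trace"] = traces;
  return out;
}

static double objective_binomial(const NumericMatrix& X, const NumericVector& y,
                                 double b0, const NumericVector& beta,
                                 const WorkState& st, double lam1,
                                 const NumericMatrix* Om) {
  int n = st.n, p = st.p;
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = b0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) eta += X(i, j) * beta[j];
    // -l = log(1 + e^eta) - y*eta, computed stably
    double l1p = (eta > 30) ? eta : std::log1p(std::exp(eta));
    loss += l1p - y[i] * eta;
  }
  loss /= n;
  double pen = 0.0;
  for (int j = 0; j < p; ++j) pen += mcp_rho(beta[j], lam1, st.gamma);
  double quad = 0.0;
  if (st.has_str) {
    for (int j = 0; j < p; ++j) {
      double uj = 0.0;
      for (int k = 0; k < p; ++k) uj += (*Om)(j, k) * beta[k];
      quad += beta[j] * uj;
    }
    quad *= st.lam2;
  }
  return loss + pen + quad;
}

// [[Rcpp::export]]
List cd_binomial_path(NumericMatrix X, NumericVector y,
                      Nullable<NumericMatrix> Omega, NumericVector lambda1,
                      double lambda2, double gamma,
                      double tol, int max_outer, int max_inner, bool trace) {
  int n = X.nrow(), p = X.ncol(), L = lambda1.size();
  const double PCLIP = 1e-5;
  WorkState st;
  st.n = n; st.p = p; st.gamma = gamma; st.lam2 = lambda2;
  st.has_str = (Omega.isNotNull() && lambda2 > 0);
  NumericMatrix Om_;
  const NumericMatrix* Om = NULL;
  if (st.has_str) { Om_ = NumericMatrix(Omega); Om = &Om_; }
  st.u.assign(p, 0.0);

  double ybar = mean(y);
  double b0 = std::log(ybar / (1.0 - ybar));
  NumericVector beta(p);

  NumericMatrix beta_out(p, L);
  NumericVector b0_out(L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  List traces(L);

  NumericVector eta(n), r(n);
  std::vector<double> a(p), wxx(p), xx(p);
  std::vector<bool> skip(p);
  // curvature bound: |d^2 l / d eta^2| <= 1/4, so a quadratic majorizer with
  // constant weight 1/4 guarantees descent of the true penalized objective
  // (and a_j = xx_j/4 + 2*lambda2*Omega_jj > 1/gamma for gamma > 4 on
  // standardized columns)
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = X.begin() + (size_t)j * n;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s / n;
    skip[j] = xx[j] < 1e-12;    // all-zero (constant) column: stays at 0
    wxx[j] = 0.25 * xx[j];
    a[j] = wxx[j] + (st.has_str ? 2.0 * lambda2 * (*Om)(j, j) : 0.0);
    if (!skip[j] && a[j] <= 1.0 / gamma)
      stop("coordinate curvature a <= 1/gamma at OTU %d (logistic); increase gamma or lambda2", j + 1);
  }

  for (int l = 0; l < L; ++l) {
    double lam1 = lambda1[l];
    bool converged = false;
    int outer = 0;
    std::vector<double> objtr;
    double obj_old = objective_binomial(X, y, b0, beta, st, lam1, Om);
    if (trace) objtr.push_back(obj_old);
    for (outer = 0; outer < max_outer; ++outer) {
      NumericVector beta_prev = clone(beta);
      double b0_prev = b0;
      // working residual of the majorizer: z - eta = 4 (y - p)
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
        double pi = 1.0 / (1.0 + std::exp(-e));
        if (pi < PCLIP) pi = PCLIP;
        if (pi > 1.0 - PCLIP) pi = 1.0 - PCLIP;
        r[i] = 4.0 * (y[i] - pi);
      }
      if (st.has_str) {
        for (int j = 0; j < p; ++j) {
          double uj = 0.0;
          for (int k = 0; k < p; ++k) uj += (*Om)(j, k) * beta[k];
          st.u[j] = uj;
        }
      } else st.u.assign(p, 0.0);
      // weighted coordinate descent on the working response
      for (int inner = 0; inner < max_inner; ++inner) {
        double maxd = 0.0;
        // intercept (unpenalized, constant weight)
        double rsum = 0.0;
        for (int i = 0; i < n; ++i) rsum += r[i];
        double d0 = rsum / n;
        if (d0 != 0.0) { b0 += d0; for (int i = 0; i < n; ++i) r[i] -= d0; }
        for (int j = 0; j < p; ++j) {
          if (skip[j]) continue;
          double xwr = 0.0;
          const double* xj = X.begin() + (size_t)j * n;
          for (int i = 0; i < n; ++i) xwr += xj[i] * r[i];
          xwr *= 0.25;
          double b = xwr / n + wxx[j] * beta[j];
          if (st.has_str) b -= 2.0 * lambda2 * (st.u[j] - (*Om)(j, j) * beta[j]);
          double bn = mcp_update(a[j], b, lam1, gamma);
          double d = bn - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
            if (st.has_str) {
              const double* oj = Om->begin() + (size_t)j * st.p;
              for (int q = 0; q < p; ++q) st.u[q] += oj[q] * d;
            }
            beta[j] = bn;
            double ad = std::fabs(d);
            if (ad > maxd) maxd = ad;
          }
        }
        double bmax2 = max(abs(beta));
        if (maxd < tol * std::max(1.0, bmax2)) break;
      }
      // step-halving safeguard on the penalized objective
      double obj_new = objective_binomial(X, y, b0, beta, st, lam1, Om);
      int halvings = 0;
      while (obj_new > obj_old + 1e-12 && halvings < 10) {
        for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + beta_prev[j]);
        b0 = 0.5 * (b0 + b0_prev);
        obj_new = objective_binomial(X, y, b0, beta, st, lam1, Om);
        ++halvings;
      }
      if (trace) objtr.push_back(obj_new);
      double maxstep = std::fabs(b0 - b0_prev);
      for (int j = 0; j < p; ++j)
        maxstep = std::max(maxstep, std::fabs(beta[j] - beta_prev[j]));
      obj_old = obj_new;
      double bmax3 = max(abs(beta));
      if (maxstep < tol * std::max(1.0, bmax3)) { converged = true; ++outer; break; }
    }
    beta_out(_, l) = beta;
    b0_out[l] = b0;
    iters[l] = outer;
    conv[l] = converged;
    if (trace) traces[l] = wrap(objtr);
  }

  List out = List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                          _["n_iter"] = iters, _["converged"] = conv);
  if (trace) out["objective_trace"] = traces;
  return out;
}
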