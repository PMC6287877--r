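// Profile-likelihood machinery for the discrete Gamma-GPD spliced model.
// The likelihood factorizes across bulk and tail given a threshold u and the
// plug-in phi = n_u / n, so each candidate threshold needs two 2-parameter
// maximizations; a compact Nelder-Mead with warm starts keeps a full grid
// search over every unique observed clone size fast.

#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

static const double BIG = 1e12;

// log survival of the continuous GPD at excess z >= 0
static inline double lsurv(double z, double sigma, double xi) {
  if (z <= 0.0) return 0.0;
  if (std::fabs(xi) < 1e-8) return -z / sigma;
  double t = xi * z / sigma;
  if (1.0 + t <= 0.0) return R_NegInf;
  return -std::log1p(t) / xi;
}

// negative log-likelihood of the discrete GPD on tabulated tail counts
static double tail_nll(double lsig, double xi,
                       const double* xv, const double* fr, int k, double u) {
  if (!R_finite(lsig) || !R_finite(xi) || lsig > 40.0 || lsig < -40.0 ||
      std::fabs(xi) > 50.0) return BIG;
  double sigma = std::exp(lsig);
  double s = 0.0;
  for (int i = 0; i < k; ++i) {
    double l1 = lsurv(xv[i] - u, sigma, xi);
    if (l1 == R_NegInf) return BIG;  // observation beyond the xi < 0 bound
    double l2 = lsurv(xv[i] + 1.0 - u, sigma, xi);
    double lg;
    if (l2 == R_NegInf) {
      lg = l1;
    } else {
      double d = l2 - l1;
      if (d >= 0.0) return BIG;
      lg = l1 + std::log(-std::expm1(d));
    }
    if (!R_finite(lg)) return BIG;
    s += fr[i] * lg;
  }
  return -s;
}

// negative log-likelihood of the truncated discrete Gamma on tabulated bulk
// counts; support {lo, ..., u-1} with lo = 0 or 1
static double bulk_nll(double la, double lb,
                       const double* xv, const double* fr, int k,
                       double u, bool include_zero) {
  if (!R_finite(la) || !R_finite(lb) || la > 20.0 || la < -20.0 ||
      lb > 20.0 || lb < -20.0) return BIG;
  double a = std::exp(la), b = std::exp(lb);
  double scale = 1.0 / b;
  double Z = R::pgamma(u, a, scale, 1, 0);
  if (!include_zero) Z -= R::pgamma(1.0, a, scale, 1, 0);
  if (!(Z > 0.0)) return BIG;
  double s = 0.0, n = 0.0;
  double mean = a * scale;
  for (int i = 0; i < k; ++i) {
    // difference taken on whichever tail is small to avoid cancellation
    double h;
    if (xv[i] < mean) {
      h = R::pgamma(xv[i] + 1.0, a, scale, 1, 0) -
          R::pgamma(xv[i], a, scale, 1, 0);
    } else {
      h = R::pgamma(xv[i], a, scale, 0, 0) -
          R::pgamma(xv[i] + 1.0, a, scale, 0, 0);
    }
    if (!(h > 0.0)) return BIG;
    s += fr[i] * std::log(h);
    n += fr[i];
  }
  return -(s - n * std::log(Z));
}

struct NMFit { double p1, p2, f; bool conv; };

// 2-parameter Nelder-Mead (reflection/expansion/contraction/shrink)
static NMFit nelder_mead2(const std::function<double(double, double)>& f,
                          double x1, double x2, double s1, double s2,
                          double tol, int maxit) {
  double vx[3][2] = { {x1, x2}, {x1 + s1, x2}, {x1, x2 + s2} };
  double vf[3];
  for (int i = 0; i < 3; ++i) vf[i] = f(vx[i][0], vx[i][1]);
  int it = 0;
  for (; it < maxit; ++it) {
    // order: lo, mid, hi
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (vf[i] < vf[lo]) lo = i;
      if (vf[i] > vf[hi]) hi = i;
    }
    int mid = 3 - lo - hi;
    if (lo == hi) { mid = 1; hi = 2; }
    if (vf[hi] - vf[lo] < tol * (std::fabs(vf[lo]) + 1.0)) break;
    double pspread = std::fabs(vx[0][0] - vx[1][0]) + std::fabs(vx[0][0] - vx[2][0]) +
                     std::fabs(vx[0][1] - vx[1][1]) + std::fabs(vx[0][1] - vx[2][1]);
    if (pspread < 1e-7) break;
    double c1 = 0.5 * (vx[lo][0] + vx[mid][0]);
    double c2 = 0.5 * (vx[lo][1] + vx[mid][1]);
    double r1 = c1 + (c1 - vx[hi][0]);
    double r2 = c2 + (c2 - vx[hi][1]);
    double fr_ = f(r1, r2);
    if (fr_ < vf[lo]) {
      double e1 = c1 + 2.0 * (c1 - vx[hi][0]);
      double e2 = c2 + 2.0 * (c2 - vx[hi][1]);
      double fe = f(e1, e2);
      if (fe < fr_) { vx[hi][0] = e1; vx[hi][1] = e2; vf[hi] = fe; }
      else { vx[hi][0] = r1; vx[hi][1] = r2; vf[hi] = fr_; }
    } else if (fr_ < vf[mid]) {
      vx[hi][0] = r1; vx[hi][1] = r2; vf[hi] = fr_;
    } else {
      double k1, k2;
      if (fr_ < vf[hi]) { k1 = c1 + 0.5 * (r1 - c1); k2 = c2 + 0.5 * (r2 - c2); }
      else { k1 = c1 + 0.5 * (vx[hi][0] - c1); k2 = c2 + 0.5 * (vx[hi][1] - c2); }
      double fk = f(k1, k2);
      if (fk < std::min(vf[hi], fr_)) {
        vx[hi][0] = k1; vx[hi][1] = k2; vf[hi] = fk;
      } else {  // shrink toward lo
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          vx[i][0] = vx[lo][0] + 0.5 * (vx[i][0] - vx[lo][0]);
          vx[i][1] = vx[lo][1] + 0.5 * (vx[i][1] - vx[lo][1]);
          vf[i] = f(vx[i][0], vx[i][1]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (vf[i] < vf[lo]) lo = i;
  NMFit out;
  out.p1 = vx[lo][0]; out.p2 = vx[lo][1]; out.f = vf[lo];
  out.conv = (it < maxit) && (vf[lo] < BIG);
  return out;
}

static NMFit best_of(const std::function<double(double, double)>& f,
                     const std::vector<std::pair<double, double>>& starts,
                     double s1, double s2, double tol, int maxit) {
  NMFit best; best.f = R_PosInf; best.conv = false; best.p1 = best.p2 = NA_REAL;
  for (size_t i = 0; i < starts.size(); ++i) {
    NMFit r = nelder_mead2(f, starts[i].first, starts[i].second,
                           s1, s2, tol, maxit);
    if (r.f < best.f) best = r;
  }
  return best;
}

// method-of-moments start for the bulk Gamma in (log alpha, log mean)
// coordinates (mean = alpha / beta); this parameterization keeps the
// likelihood valley roughly axis-aligned, which Nelder-Mead likes
static std::pair<double, double> mom_start(const double* xv, const double* fr,
                                           int k) {
  double n = 0.0, m = 0.0;
  for (int i = 0; i < k; ++i) { n += fr[i]; m += fr[i] * xv[i]; }
  m /= n;
  double v = 0.0;
  for (int i = 0; i < k; ++i) v += fr[i] * (xv[i] - m) * (xv[i] - m);
  v /= std::max(n - 1.0, 1.0);
  if (!(v > 0.0) || !(m > 0.0)) return std::make_pair(0.0, std::log(10.0));
  return std::make_pair(std::log(m * m / v), std::log(m));
}

// Hill-type start for the tail mapped through the Pareto-GPD identity:
// alpha_d = n_u / sum(log(x / u)) then sigma = u / alpha_d, xi = 1 / alpha_d
static std::pair<double, double> hill_start(const double* xv, const double* fr,
                                            int k, double u) {
  double n = 0.0, s = 0.0;
  for (int i = 0; i < k; ++i) {
    n += fr[i];
    s += fr[i] * std::log(xv[i] / u);
  }
  if (!(s > 0.0)) return std::make_pair(std::log(std::max(u, 2.0) / 2.0), 0.5);
  double ad = n / s;
  double xi = 1.0 / ad;
  if (xi > 20.0) xi = 20.0;
  return std::make_pair(std::log(std::max(u / ad, 1e-3)), xi);
}

// Fit both components at a single threshold.  xu/fr: the tabulated sample
// (sorted unique sizes and their clone frequencies); warm: optional
// c(la, lb, lsig, xi) starting point from a neighbouring threshold.
// [[Rcpp::export]]
List fit_threshold_cpp(NumericVector xu, NumericVector fr, double u,
                       bool include_zero, NumericVector warm,
                       bool extra_starts = true,
                       double tol = 1e-9, int maxit = 300) {
  int m = xu.size();
  int t0 = 0;
  while (t0 < m && xu[t0] < u) ++t0;   // first tail index
  const double* xp = REAL(xu);
  const double* fp = REAL(fr);
  int kb = t0, kt = m - t0;
  double nb = 0.0, nt = 0.0;
  for (int i = 0; i < kb; ++i) nb += fp[i];
  for (int i = t0; i < m; ++i) nt += fp[i];
  if (kb < 1 || kt < 1) stop("threshold leaves an empty component");

  // bulk optimized over (log alpha, log mean); beta = alpha / mean
  auto fb = [&](double la, double lm) {
    return bulk_nll(la, la - lm, xp, fp, kb, u, include_zero);
  };
  auto ft = [&](double ls, double xi) {
    return tail_nll(ls, xi, xp + t0, fp + t0, kt, u);
  };

  std::vector<std::pair<double, double>> sb, st;
  bool has_warm = warm.size() == 4 && R_finite(warm[0]);
  if (has_warm) {
    sb.push_back(std::make_pair(warm[0], warm[1]));
    st.push_back(std::make_pair(warm[2], warm[3]));
  }
  if (extra_starts || !has_warm) {
    sb.push_back(mom_start(xp, fp, kb));
    sb.push_back(std::make_pair(0.0, std::log(10.0)));
    st.push_back(hill_start(xp + t0, fp + t0, kt, u));
    st.push_back(std::make_pair(std::log(std::max(u, 2.0) / 2.0), 0.5));
  }

  double step = has_warm ? 0.02 : 0.15;
  NMFit rb = best_of(fb, sb, step, step, tol, maxit);
  NMFit rt = best_of(ft, st, step, step / 2.0, tol, maxit);

  double n = nb + nt;
  double phi = nt / n;
  double ll = R_NegInf;
  bool conv = rb.f < BIG && rt.f < BIG &&
              R_finite(rb.f) && R_finite(rt.f);
  if (conv) {
    ll = nb * std::log(1.0 - phi) + nt * std::log(phi) - rb.f - rt.f;
  }
  return List::create(
    _["alpha"] = std::exp(rb.p1), _["beta"] = std::exp(rb.p1 - rb.p2),
    _["sigma"] = std::exp(rt.p1), _["xi"] = rt.p2,
    _["phi"] = phi, _["loglik"] = ll, _["converged"] = conv,
    _["n_bulk"] = nb, _["n_tail"] = nt,
    _["warm"] = NumericVector::create(rb.p1, rb.p2, rt.p1, rt.p2));
}

static inline double hval(double x, double a, double scale) {
  if (x < a * scale) {
    return R::pgamma(x + 1.0, a, scale, 1, 0) - R::pgamma(x, a, scale, 1, 0);
  }
  return R::pgamma(x, a, scale, 0, 0) - R::pgamma(x + 1.0, a, scale, 0, 0);
}

// Full profile search over candidate thresholds (ascending).
//
// Moving the threshold up one unique size shifts only a handful of clones
// from tail to bulk, so the bulk MLE drifts very slowly: the bulk component
// is fully re-optimized only when its clone count has grown by
// `bulk_refresh` (or after `refresh_every` candidates), and in between the
// bulk term is updated incrementally at the last optimized parameters.
// The tail is re-optimized at every candidate, warm-started through the
// threshold-stability map (u, sigma, xi) -> (u', sigma + xi (u' - u), xi),
// which is exact for GPD data and therefore an excellent initial point.
// [[Rcpp::export]]
NumericMatrix profile_spliced_cpp(NumericVector xu, NumericVector fr,
                                  NumericVector ucand, bool include_zero,
                                  double bulk_refresh = 0.01,
                                  int refresh_every = 250,
                                  double tol = 1e-9, int maxit = 300) {
  int m = xu.size(), nc = ucand.size();
  const double* xp = REAL(xu);
  const double* fp = REAL(fr);
  std::vector<double> cum(m + 1, 0.0);
  for (int i = 0; i < m; ++i) cum[i + 1] = cum[i] + fp[i];
  double ntot = cum[m];
  NumericMatrix out(nc, 8);
  colnames(out) = CharacterVector::create("u", "alpha", "beta", "sigma",
                                          "xi", "phi", "loglik", "converged");
  bool have = false;
  double la = 0, lm = 0, lsig = 0, xi = 0;
  double S_stale = 0, nb_lastfull = 0, u_prev = 0;
  int t_stale = 0, j_lastfull = -1000000, t0 = 0;
  double lo = include_zero ? 0.0 : 1.0;

  for (int j = 0; j < nc; ++j) {
    double u = ucand[j];
    while (t0 < m && xp[t0] < u) ++t0;
    double nb = cum[t0], nt = ntot - cum[t0];
    int kt = m - t0;
    if (t0 < 1 || kt < 1) stop("candidate threshold leaves an empty component");

    auto fb = [&](double a1, double a2) {
      return bulk_nll(a1, a1 - a2, xp, fp, t0, u, include_zero);
    };
    auto ft = [&](double a1, double a2) {
      return tail_nll(a1, a2, xp + t0, fp + t0, kt, u);
    };

    bool fresh = !have ||
      (nb - nb_lastfull) / std::max(nb_lastfull, 1.0) > bulk_refresh ||
      (j - j_lastfull) >= refresh_every;
    double bnll;
    if (fresh) {
      std::vector<std::pair<double, double>> sb;
      if (have) sb.push_back(std::make_pair(la, lm));
      sb.push_back(mom_start(xp, fp, t0));
      if (!have) sb.push_back(std::make_pair(0.0, std::log(10.0)));
      NMFit rb = best_of(fb, sb, have ? 0.03 : 0.15, have ? 0.03 : 0.15,
                         tol, maxit);
      la = rb.p1; lm = rb.p2; bnll = rb.f;
      double a = std::exp(la), scale = std::exp(lm) / a;
      double Z = R::pgamma(u, a, scale, 1, 0) -
                 (include_zero ? 0.0 : R::pgamma(lo, a, scale, 1, 0));
      S_stale = (bnll < BIG && Z > 0.0) ? nb * std::log(Z) - bnll : R_NegInf;
      t_stale = t0; nb_lastfull = nb; j_lastfull = j;
    } else {
      double a = std::exp(la), scale = std::exp(lm) / a;
      for (int i = t_stale; i < t0; ++i) {
        double h = hval(xp[i], a, scale);
        S_stale += (h > 0.0) ? fp[i] * std::log(h) : R_NegInf;
      }
      t_stale = t0;
      double Z = R::pgamma(u, a, scale, 1, 0) -
                 (include_zero ? 0.0 : R::pgamma(lo, a, scale, 1, 0));
      bnll = (R_finite(S_stale) && Z > 0.0) ? -(S_stale - nb * std::log(Z))
                                            : BIG;
    }

    std::vector<std::pair<double, double>> st;
    if (have) {
      double sig_map = std::exp(lsig) + xi * (u - u_prev);
      st.push_back(std::make_pair(
        std::log(sig_map > 1e-6 ? sig_map : std::exp(lsig)), xi));
    }
    if (!have || fresh) st.push_back(hill_start(xp + t0, fp + t0, kt, u));
    if (!have) st.push_back(std::make_pair(std::log(std::max(u, 2.0) / 2.0), 0.5));
    NMFit rt = best_of(ft, st, have ? 0.02 : 0.15, have ? 0.01 : 0.08,
                       tol, maxit);
    lsig = rt.p1; xi = rt.p2;

    double phi = nt / ntot;
    bool conv = bnll < BIG && rt.f < BIG && R_finite(bnll) && R_finite(rt.f);
    double ll = conv ? nb * std::log(1.0 - phi) + nt * std::log(phi) -
                       bnll - rt.f
                     : R_NegInf;
    out(j, 0) = u;
    out(j, 1) = std::exp(la);
    out(j, 2) = std::exp(la - lm);
    out(j, 3) = std::exp(lsig);
    out(j, 4) = xi;
    out(j, 5) = phi;
    out(j, 6) = ll;
    out(j, 7) = conv ? 1.0 : 0.0;
    have = true; u_prev = u;
  }
  return out;
}
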