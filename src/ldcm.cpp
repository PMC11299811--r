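// Core numerics for the LDC package: discrete random-walk simulation of the
// drift-diffusion decision process, the quantile/bin SSE objective evaluated
// on a fixed noise pool (common random numbers), and the probit-logistic
// constant search. Everything here is called from thin R wrappers.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// Sequential reader over a pre-drawn N(0,1) pool with wraparound. The pool
// is stored in single precision behind an external pointer: the increments
// only need simulation accuracy, and halving the memory traffic roughly
// halves the cost of the walk loop.
struct PoolReader {
  const float* p;
  int n;
  int idx;
  PoolReader(const float* p_, int n_, int start) : p(p_), n(n_), idx(start % n_) {}
  inline double next() {
    double v = p[idx];
    if (++idx >= n) idx = 0;
    return v;
  }
};

typedef std::vector<float> FloatPool;

const FloatPool& get_pool(SEXP pool) {
  Rcpp::XPtr<FloatPool> xp(pool);
  return *xp;
}

// Walk from z*a until |e| >= a. Returns +1/-1 for the bound hit, 0 if the
// walk exceeds max_steps (degenerate parameters).
inline int walk_to_bound(PoolReader& pr, double v_tau, double c, double a,
                         double z, int max_steps, int& steps_out) {
  double e = z * a;
  for (int s = 1; s <= max_steps; ++s) {
    e += v_tau + c * pr.next();
    if (e >= a)  { steps_out = s; return  1; }
    if (e <= -a) { steps_out = s; return -1; }
  }
  return 0;
}

inline double walk_free(PoolReader& pr, double e0, double v_tau, double c, int steps) {
  double e = e0;
  for (int s = 0; s < steps; ++s) e += v_tau + c * pr.next();
  return e;
}

// Confidence-bin SSE over trials of one condition (cond == -1: all), with
// per-condition normalization against obs (ncond x 12, corrects 0..5 then
// errors 6..11). L holds logit(k/6), k = 1..5; the bin rule is right-closed
// (confidence > k/6 moves the trial up a bin).
struct ConfData {
  const double* u;      // x * total evidence
  const double* s;      // t^gamma
  const int* acc;
  const int* cond;
  const int* diff;      // difficulty level (0-based)
  int nlev;
  int n;
  int ncond;
  const double* obs;    // ncond x (12*nlev), column-major: obs[c + ncond*j]
  const int* ncond_trials;
};

static const double LOGIT_EDGE[5] = {
  -1.6094379124341003, -0.6931471805599453, 0.0,
   0.6931471805599453,  1.6094379124341003 };

double conf_sse(const ConfData& d, double alpha, double beta, int target_cond) {
  int cells = 12 * d.nlev;
  std::vector<double> cnt(cells * d.ncond, 0.0);
  for (int i = 0; i < d.n; ++i) {
    int c = d.cond[i];
    if (target_cond >= 0 && c != target_cond) continue;
    double w = alpha * d.u[i] + beta;
    double si = d.s[i];
    int bin = 0;
    for (int k = 0; k < 5; ++k) if (w > si * LOGIT_EDGE[k]) ++bin;
    cnt[cells * c + 12 * d.diff[i] + (d.acc[i] ? bin : 6 + bin)] += 1.0;
  }
  double sse = 0.0;
  for (int c = 0; c < d.ncond; ++c) {
    if (target_cond >= 0 && c != target_cond) continue;
    double nc = (double)d.ncond_trials[c];
    if (nc <= 0) continue;
    for (int j = 0; j < cells; ++j) {
      double diff = cnt[cells * c + j] / nc - d.obs[c + d.ncond * j];
      sse += diff * diff;
    }
  }
  return sse;
}

// Two-level grid plus Nelder-Mead profile of (alpha, beta) on the confidence
// term. The binned objective is piecewise constant at the single-trial
// granularity; the grid locates the basin and Nelder-Mead refines within it.
// A tiny quadratic tie-break on beta (BETA_RIDGE) pins the flat ridge that
// saturated-confidence data leave in the (alpha, beta) plane; sse_out is the
// unpenalized value at the returned point.
static const double BETA_RIDGE = 1e-6;

void profile_ab(const ConfData& d, int target_cond,
                double alo, double ahi, double blo, double bhi, int dense,
                double& alpha_out, double& beta_out, double& sse_out) {
  const int NA1 = dense ? 31 : 11, NB1 = dense ? 15 : 5;
  double best_a = alo, best_b = 0.0, best = R_PosInf;
  double astep = (ahi - alo) / (NA1 - 1), bstep = (bhi - blo) / (NB1 - 1);
  for (int ia = 0; ia < NA1; ++ia) {
    double av = alo + ia * astep;
    for (int ib = 0; ib < NB1; ++ib) {
      double bv = blo + ib * bstep;
      double v = conf_sse(d, av, bv, target_cond) + BETA_RIDGE * bv * bv;
      if (v < best) { best = v; best_a = av; best_b = bv; }
    }
  }
  // refine on an 11 x 9 grid spanning one coarse step around the best point
  double alo2 = std::max(alo, best_a - astep), ahi2 = std::min(ahi, best_a + astep);
  double blo2 = std::max(blo, best_b - bstep), bhi2 = std::min(bhi, best_b + bstep);
  const int NA2 = dense ? 13 : 7, NB2 = dense ? 11 : 5;
  for (int ia = 0; ia < NA2; ++ia) {
    double av = alo2 + ia * (ahi2 - alo2) / (NA2 - 1);
    for (int ib = 0; ib < NB2; ++ib) {
      double bv = blo2 + ib * (bhi2 - blo2) / (NB2 - 1);
      double v = conf_sse(d, av, bv, target_cond) + BETA_RIDGE * bv * bv;
      if (v < best) { best = v; best_a = av; best_b = bv; }
    }
  }
  // Nelder-Mead (reflection/expansion/contraction/shrink), clamped to bounds
  auto f = [&](double av, double bv) {
    av = std::min(std::max(av, alo), ahi);
    bv = std::min(std::max(bv, blo), bhi);
    return conf_sse(d, av, bv, target_cond) + BETA_RIDGE * bv * bv;
  };
  double px[3] = { best_a, best_a + 0.5 * astep, best_a };
  double py[3] = { best_b, best_b, best_b + 0.5 * bstep };
  double pv[3] = { f(px[0], py[0]), f(px[1], py[1]), f(px[2], py[2]) };
  const int nm_iter = dense ? 150 : 50;
  for (int it = 0; it < nm_iter; ++it) {
    int lo = 0, hi = 0;
    for (int k = 1; k < 3; ++k) {
      if (pv[k] < pv[lo]) lo = k;
      if (pv[k] > pv[hi]) hi = k;
    }
    if (pv[hi] - pv[lo] < 1e-12) break;
    double cx = 0, cy = 0;
    for (int k = 0; k < 3; ++k) if (k != hi) { cx += px[k]; cy += py[k]; }
    cx /= 2; cy /= 2;
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double rv = f(rx, ry);
    if (rv < pv[lo]) {
      double ex = cx + 2 * (cx - px[hi]), ey = cy + 2 * (cy - py[hi]);
      double ev = f(ex, ey);
      if (ev < rv) { px[hi] = ex; py[hi] = ey; pv[hi] = ev; }
      else { px[hi] = rx; py[hi] = ry; pv[hi] = rv; }
    } else if (rv < pv[hi]) {
      px[hi] = rx; py[hi] = ry; pv[hi] = rv;
    } else {
      double kx = cx + 0.5 * (px[hi] - cx), ky = cy + 0.5 * (py[hi] - cy);
      double kv = f(kx, ky);
      if (kv < pv[hi]) { px[hi] = kx; py[hi] = ky; pv[hi] = kv; }
      else {
        for (int k = 0; k < 3; ++k) {
          if (k == lo) continue;
          px[k] = px[lo] + 0.5 * (px[k] - px[lo]);
          py[k] = py[lo] + 0.5 * (py[k] - py[lo]);
          pv[k] = f(px[k], py[k]);
        }
      }
    }
  }
  int lo = 0;
  for (int k = 1; k < 3; ++k) if (pv[k] < pv[lo]) lo = k;
  alpha_out = std::min(std::max(px[lo], alo), ahi);
  beta_out  = std::min(std::max(py[lo], blo), bhi);
  sse_out = conf_sse(d, alpha_out, beta_out, target_cond);
}

} // namespace

// Freeze a pre-drawn N(0,1) pool (from R's RNG) into the single-precision
// buffer the objective reads.
// [[Rcpp::export]]
SEXP cpp_make_pool(NumericVector x) {
  Rcpp::XPtr<FloatPool> xp(new FloatPool(x.begin(), x.end()), true);
  return xp;
}

// Simulate decision walks with R's RNG (used by the user-facing generator).
// Returns a matrix with columns: choice (+1/-1, NA on non-termination),
// first-passage time in seconds, evidence at decision (clipped to +/- a).
// [[Rcpp::export]]
NumericMatrix cpp_walk_trials(NumericVector v_signed, double a, double z,
                              double sigma, double tau, double max_t) {
  int n = v_signed.size();
  int max_steps = (int)std::floor(max_t / tau);
  double c = sigma * std::sqrt(tau);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double e = z * a, v_tau = v_signed[i] * tau;
    int hit = 0, steps = 0;
    for (int s = 1; s <= max_steps; ++s) {
      e += v_tau + c * norm_rand();
      if (e >= a)  { hit = 1;  steps = s; break; }
      if (e <= -a) { hit = -1; steps = s; break; }
    }
    if (hit == 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
    } else {
      out(i, 0) = hit;
      out(i, 1) = steps * tau;
      out(i, 2) = hit * a;
    }
  }
  return out;
}

// Unbounded post-decisional walk with R's RNG; duration 0 is the identity.
// [[Rcpp::export]]
NumericVector cpp_post_walk(NumericVector e0, NumericVector drift,
                            NumericVector dur, double sigma, double tau) {
  int n = e0.size();
  double c = sigma * std::sqrt(tau);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int steps = (int)std::lround(dur[i] / tau);
    double e = e0[i], v_tau = drift[i] * tau;
    for (int s = 0; s < steps; ++s) e += v_tau + c * norm_rand();
    out[i] = e;
  }
  return out;
}

// Simulate the prediction set on the noise pool and return per-trial features.
// All walks use positive drift (summaries are symmetric in stimulus sign);
// u is evidence folded into the frame of the chosen option.
// Columns: acc, decision_rt (incl. ter), t_acc, t_resp, u, e_total.
// Trials breaching max_t get acc = NA.
// [[Rcpp::export]]
NumericMatrix cpp_sim_features(NumericVector theta, IntegerVector sim_diff,
                               NumericVector sim_dur, SEXP pool,
                               int stride, double z, double sigma, double tau,
                               double max_t, bool post) {
  double ter = theta[0], a = theta[1];
  int nlev = theta.size() - 2;
  int n = sim_diff.size();
  int max_steps = (int)std::floor(max_t / tau);
  double c = sigma * std::sqrt(tau);
  NumericMatrix out(n, 6);
  const FloatPool& fp = get_pool(pool);
  const float* pp = fp.data();
  int pn = (int)fp.size();
  for (int i = 0; i < n; ++i) {
    int d = sim_diff[i];
    if (d < 0 || d >= nlev) stop("difficulty index out of range");
    double v = theta[2 + d];
    PoolReader pr(pp, pn, (int)(((long long)i * stride) % pn));
    int steps = 0;
    int hit = walk_to_bound(pr, v * tau, c, a, z, max_steps, steps);
    if (hit == 0) {
      for (int j = 0; j < 6; ++j) out(i, j) = NA_REAL;
      continue;
    }
    double dt = steps * tau;
    double e_total = hit * a;
    double dur = post ? sim_dur[i] : 0.0;
    if (post && dur > 0) {
      int psteps = (int)std::lround(dur / tau);
      e_total = walk_free(pr, e_total, v * tau, c, psteps);
    }
    int acc = (hit == 1) ? 1 : 0;
    out(i, 0) = acc;
    out(i, 1) = dt + ter;
    out(i, 2) = dt + dur;          // accumulation time
    out(i, 3) = dt + ter + dur;    // response time (decision RT + confidence RT)
    out(i, 4) = hit * e_total;     // chosen-option frame
    out(i, 5) = e_total;
  }
  return out;
}

// Full quantile/bin SSE objective for one DDM parameter vector.
// theta = (ter, a, v_1..v_nlev). Observed summaries are per condition.
// The RT term is difficulty-resolved: cut_cor/cut_err are ncond x (5*nlev)
// cutoffs (columns 5*d..5*d+4 for difficulty d; NA = class unobserved) and
// obs_rt is ncond x (12*nlev) joint proportions over (difficulty x accuracy
// x group), blocks of 12 per difficulty (corrects 1..6 then errors 1..6).
// The confidence term is pooled per condition: obs_cj is ncond x 12.
// mode: 0 = RT term only; 1 = profile (alpha, beta) per condition;
//       2 = profile one shared (alpha, beta); 3 = explicit ab (ncond x 2).
// [[Rcpp::export]]
List cpp_fit_objective(NumericVector theta, IntegerVector sim_diff,
                       IntegerVector sim_cond, NumericVector sim_dur,
                       SEXP pool, int stride, double z, double sigma,
                       double tau, double max_t, double gamma,
                       NumericMatrix cut_cor, NumericMatrix cut_err,
                       NumericMatrix obs_rt, NumericMatrix obs_cj,
                       int mode, NumericMatrix ab, NumericVector ab_bounds,
                       int time_mode, int dense) {
  double ter = theta[0], a = theta[1];
  int nlev = theta.size() - 2;
  int n = sim_diff.size();
  int ncond = obs_rt.nrow();
  int max_steps = (int)std::floor(max_t / tau);
  double c = sigma * std::sqrt(tau);
  const FloatPool& fp = get_pool(pool);
  const float* pp = fp.data();
  int pn = (int)fp.size();
  bool need_conf = (mode != 0);

  if (obs_rt.ncol() != 12 * nlev || cut_cor.ncol() != 5 * nlev ||
      (need_conf && obs_cj.ncol() != 12 * nlev)) {
    stop("summary shape does not match the number of difficulty levels");
  }
  std::vector<double> u(need_conf ? n : 0), s(need_conf ? n : 0);
  std::vector<int> acc_v(need_conf ? n : 0);
  std::vector<double> rt_cnt(12 * nlev * ncond, 0.0);
  std::vector<int> ntr(ncond, 0);

  for (int i = 0; i < n; ++i) ntr[sim_cond[i]]++;

  for (int i = 0; i < n; ++i) {
    int d = sim_diff[i], cc = sim_cond[i];
    double v = theta[2 + d];
    PoolReader pr(pp, pn, (int)(((long long)i * stride) % pn));
    int steps = 0;
    int hit = walk_to_bound(pr, v * tau, c, a, z, max_steps, steps);
    if (hit == 0)
      return List::create(_["ok"] = false, _["sse"] = R_PosInf);
    double dt = steps * tau;
    double rt = dt + ter;
    int acc = (hit == 1) ? 1 : 0;
    // RT group against the observed cutoffs of this condition's
    // (difficulty, accuracy) class
    NumericMatrix& cuts = acc ? cut_cor : cut_err;
    double* cell = &rt_cnt[12 * nlev * cc + 12 * d];
    if (NumericVector::is_na(cuts(cc, 5 * d))) {
      // class unobserved: spread the trial's mass equally over the 6 groups
      for (int g = 0; g < 6; ++g) cell[acc ? g : 6 + g] += 1.0 / 6.0;
    } else {
      int g = 0;
      for (int k = 0; k < 5; ++k) if (rt > cuts(cc, 5 * d + k)) ++g;
      cell[acc ? g : 6 + g] += 1.0;
    }
    if (need_conf) {
      double dur = sim_dur[i];
      double e_total = hit * a;
      if (dur > 0) {
        int psteps = (int)std::lround(dur / tau);
        e_total = walk_free(pr, e_total, v * tau, c, psteps);
      }
      double t_conf = (time_mode == 0) ? (dt + dur) : (dt + ter + dur);
      u[i] = hit * e_total;
      s[i] = std::pow(t_conf, gamma);
      acc_v[i] = acc;
    }
  }

  double sse_rt = 0.0;
  for (int cc = 0; cc < ncond; ++cc) {
    double nc = (double)ntr[cc];
    for (int j = 0; j < 12 * nlev; ++j) {
      double diff = rt_cnt[12 * nlev * cc + j] / nc - obs_rt(cc, j);
      sse_rt += diff * diff;
    }
  }

  if (!need_conf)
    return List::create(_["ok"] = true, _["sse"] = sse_rt, _["sse_rt"] = sse_rt,
                        _["sse_cj"] = 0.0, _["ab"] = R_NilValue);

  ConfData cd;
  cd.u = u.data(); cd.s = s.data(); cd.acc = acc_v.data();
  std::vector<int> cond_v(sim_cond.begin(), sim_cond.end());
  std::vector<int> diff_v(sim_diff.begin(), sim_diff.end());
  cd.cond = cond_v.data(); cd.diff = diff_v.data(); cd.nlev = nlev;
  cd.n = n; cd.ncond = ncond; cd.obs = REAL(obs_cj);
  cd.ncond_trials = ntr.data();

  NumericMatrix ab_out(ncond, 2);
  double sse_cj = 0.0;
  if (mode == 1) {
    for (int cc = 0; cc < ncond; ++cc) {
      double av, bv, sv;
      profile_ab(cd, cc, ab_bounds[0], ab_bounds[1], ab_bounds[2], ab_bounds[3],
                 dense, av, bv, sv);
      ab_out(cc, 0) = av; ab_out(cc, 1) = bv;
      sse_cj += sv;
    }
  } else if (mode == 2) {
    double av, bv, sv;
    profile_ab(cd, -1, ab_bounds[0], ab_bounds[1], ab_bounds[2], ab_bounds[3],
               dense, av, bv, sv);
    for (int cc = 0; cc < ncond; ++cc) { ab_out(cc, 0) = av; ab_out(cc, 1) = bv; }
    sse_cj = sv;
  } else {
    for (int cc = 0; cc < ncond; ++cc) {
      sse_cj += conf_sse(cd, ab(cc, 0), ab(cc, 1), cc);
      ab_out(cc, 0) = ab(cc, 0); ab_out(cc, 1) = ab(cc, 1);
    }
  }

  return List::create(_["ok"] = true, _["sse"] = sse_rt + sse_cj,
                      _["sse_rt"] = sse_rt, _["sse_cj"] = sse_cj,
                      _["ab"] = ab_out);
}

// Joint (accuracy x bin) confidence proportions for given (alpha, beta) on
// pre-simulated features; order: corrects 1..6 then errors 1..6.
// [[Rcpp::export]]
NumericVector cpp_conf_props(NumericVector u, NumericVector s,
                             IntegerVector acc, double alpha, double beta) {
  int n = u.size();
  NumericVector cnt(12);
  for (int i = 0; i < n; ++i) {
    double w = alpha * u[i] + beta;
    int bin = 0;
    for (int k = 0; k < 5; ++k) if (w > s[i] * LOGIT_EDGE[k]) ++bin;
    cnt[acc[i] ? bin : 6 + bin] += 1.0;
  }
  for (int j = 0; j < 12; ++j) cnt[j] /= n;
  return cnt;
}

// Joint (accuracy x bin) proportions for an arbitrary confidence vector in
// [0, 1] (right-closed equal-width bins), used by the Bayesian-readout
// candidates.
// [[Rcpp::export]]
NumericVector cpp_bin_props(NumericVector conf, IntegerVector acc) {
  int n = conf.size();
  NumericVector cnt(12);
  for (int i = 0; i < n; ++i) {
    int bin = (int)std::ceil(conf[i] * 6.0) - 1;
    if (bin < 0) bin = 0;
    if (bin > 5) bin = 5;
    cnt[acc[i] ? bin : 6 + bin] += 1.0;
  }
  for (int j = 0; j < 12; ++j) cnt[j] /= n;
  return cnt;
}

// Grid search for the logistic constant minimizing the maximum absolute
// deviation from the standard normal CDF. The deviation is symmetric in z,
// so only z >= 0 is scanned.
// [[Rcpp::export]]
List cpp_fit_lambda(double lam_lo, double lam_hi, double lam_step,
                    double z_max, double z_step) {
  int nz = (int)std::floor(z_max / z_step) + 1;
  std::vector<double> zs(nz), phis(nz);
  for (int i = 0; i < nz; ++i) {
    zs[i] = i * z_step;
    phis[i] = R::pnorm(zs[i], 0.0, 1.0, 1, 0);
  }
  int nl = (int)std::floor((lam_hi - lam_lo) / lam_step + 1e-9) + 1;
  double best_lam = lam_lo, best_dev = R_PosInf;
  for (int j = 0; j < nl; ++j) {
    double lam = lam_lo + j * lam_step;
    double mx = 0.0;
    for (int i = 0; i < nz; ++i) {
      double d = std::fabs(phis[i] - 1.0 / (1.0 + std::exp(-lam * zs[i])));
      if (d > mx) mx = d;
    }
    if (mx < best_dev) { best_dev = mx; best_lam = lam; }
  }
  return List::create(_["lambda"] = best_lam, _["max_dev"] = best_dev);
}
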