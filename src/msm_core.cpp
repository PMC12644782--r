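// Panel-data likelihood for the four-state cognitive ageing model.
// States are 0-based here: 0 = NC, 1 = MCI, 2 = DEM, 3 = DEATH (last = absorbing).
// Censored state sets are fixed to {NC, MCI} (alive, dementia-free, stage unknown).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Model {
  int K;                 // number of states
  int death;             // absorbing state index
  arma::ivec from, to;   // allowed transitions (0-based), length nt
  arma::vec lograte;     // log hazard at ref_age, per transition
  arma::vec shape;       // Gompertz slope per transition (1/year)
  arma::mat beta;        // nt x ncovf log-HRs (effective columns)
  arma::ivec cov_idx;    // effective column -> column of X (0-based)
  arma::ivec cov_side;   // 0 = always, 1 = age <= brk only, 2 = age > brk only
  double ref_age;
  bool has_brk;
  double brk;
  bool any_shape;
};

Model build_model(const List& model) {
  Model m;
  m.K = as<int>(model["K"]);
  m.death = as<int>(model["death"]) - 1;
  m.from = as<arma::ivec>(model["from"]) - 1;
  m.to = as<arma::ivec>(model["to"]) - 1;
  m.lograte = as<arma::vec>(model["log_rate"]);
  m.shape = as<arma::vec>(model["shape"]);
  m.beta = as<arma::mat>(model["beta"]);
  m.cov_idx = as<arma::ivec>(model["cov_idx"]);
  if (m.cov_idx.n_elem > 0) m.cov_idx -= 1;
  m.cov_side = as<arma::ivec>(model["cov_side"]);
  m.ref_age = as<double>(model["ref_age"]);
  double brk = as<double>(model["age_break"]);
  m.has_brk = R_finite(brk);
  m.brk = brk;
  m.any_shape = arma::any(arma::abs(m.shape) > 0.0);
  return m;
}

void set_theta(Model& m, const arma::vec& theta) {
  const int nt = m.from.n_elem, nf = m.beta.n_cols;
  m.lograte = theta.subvec(0, nt - 1);
  m.shape = theta.subvec(nt, 2 * nt - 1);
  if (nf > 0)
    m.beta = arma::reshape(theta.subvec(2 * nt, 2 * nt + nt * nf - 1), nt, nf);
  m.any_shape = arma::any(arma::abs(m.shape) > 0.0);
}

// Intensity matrix Q(age, x): rows sum to zero, death row zero.
arma::mat qmat(const Model& m, double age, const arma::rowvec& x) {
  arma::mat Q(m.K, m.K, arma::fill::zeros);
  const bool young = !m.has_brk || age <= m.brk;
  for (arma::uword t = 0; t < m.from.n_elem; ++t) {
    double lp = m.lograte[t] + m.shape[t] * (age - m.ref_age);
    for (arma::uword j = 0; j < m.beta.n_cols; ++j) {
      const int side = m.cov_side[j];
      if (side == 0 || (side == 1 && young) || (side == 2 && !young))
        lp += m.beta(t, j) * x[m.cov_idx[j]];
    }
    // clamp so that extreme optimizer proposals stay numerically evaluable
    if (lp > 5.0) lp = 5.0;
    Q(m.from[t], m.to[t]) += std::exp(lp);
  }
  for (int r = 0; r < m.K; ++r) {
    double s = 0.0;
    for (int c = 0; c < m.K; ++c) if (c != r) s += Q(r, c);
    Q(r, r) = -s;
  }
  return Q;
}

// P(a0, a1): piecewise-constant approximation, product of matrix exponentials of
// Q(midpoint) * dt over a grid of width <= step, split additionally at the age break.
// With all shapes zero the intensities are constant within a side, so one factor
// per segment is exact.
arma::mat interval_p(const Model& m, double a0, double a1,
                     const arma::rowvec& x, double step) {
  arma::mat P(m.K, m.K, arma::fill::eye);
  if (a1 - a0 <= 1e-12) return P;
  double cuts[3];
  int nc = 0;
  cuts[nc++] = a0;
  if (m.has_brk && m.brk > a0 + 1e-12 && m.brk < a1 - 1e-12) cuts[nc++] = m.brk;
  cuts[nc++] = a1;
  for (int c = 0; c + 1 < nc; ++c) {
    const double lo = cuts[c], hi = cuts[c + 1], len = hi - lo;
    int nseg = m.any_shape ? (int)std::ceil(len / step - 1e-9) : 1;
    if (nseg < 1) nseg = 1;
    const double dt = len / nseg;
    for (int k = 0; k < nseg; ++k) {
      const double mid = lo + (k + 0.5) * dt;
      arma::mat E;
      if (!arma::expmat(E, qmat(m, mid, x) * dt)) {
        P.fill(arma::datum::nan);
        return P;
      }
      P = P * E;
    }
  }
  return P;
}

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Observation type codes: 1 known state, 2 censored {NC, MCI},
// 3 exact death (state before death unknown), 4 death with dementia in interval.
double subject_ll(const Model& m, const double* ages, const int* otype,
                  const int* ostate, int n, const arma::rowvec& x, double step) {
  if (n <= 1) return 0.0;
  arma::rowvec alpha(m.K, arma::fill::zeros);
  if (otype[0] == 1) alpha[ostate[0]] = 1.0;
  else if (otype[0] == 2) { alpha[0] = 1.0; alpha[1] = 1.0; }
  else return NEG_INF;
  double ll = 0.0;
  for (int i = 1; i < n; ++i) {
    const arma::mat P = interval_p(m, ages[i - 1], ages[i], x, step);
    const arma::rowvec a2 = alpha * P;
    double c = 0.0;
    if (otype[i] == 1) {
      c = a2[ostate[i]];
      alpha.zeros();
      alpha[ostate[i]] = 1.0;
    } else if (otype[i] == 2) {
      alpha.zeros();
      alpha[0] = a2[0];
      alpha[1] = a2[1];
      c = alpha[0] + alpha[1];
      if (c > 0.0) alpha /= c;
    } else {
      // Dementia status at death is always ascertained (registry/chart
      // review), so the two death codes partition the deaths: an exact
      // death without the dementia flag sums over the non-dementia living
      // states only, and a dementia-at-death observation restricts the
      // pre-death state to DEM (onset in the preceding interval).
      const arma::mat Q = qmat(m, ages[i], x);
      if (otype[i] == 3) {
        for (int s = 0; s < 2; ++s) c += a2[s] * Q(s, m.death);
      } else {
        c = a2[2] * Q(2, m.death);
      }
    }
    if (!(c > 0.0) || !R_finite(c)) return NEG_INF;
    ll += std::log(c);
  }
  return ll;
}

double total_ll(const Model& m, const List& data, double step,
                arma::vec* by_subject = nullptr) {
  const IntegerVector ptr = data["ptr"];
  const NumericVector ages = data["ages"];
  const IntegerVector otype = data["otype"];
  const IntegerVector ostate = data["ostate"];
  const NumericMatrix X = data["X"];
  const NumericVector w = data["w"];
  const int nsub = ptr.size() - 1;
  arma::rowvec x(std::max(1, (int)X.ncol()), arma::fill::zeros);
  double tot = 0.0;
  for (int i = 0; i < nsub; ++i) {
    for (int j = 0; j < X.ncol(); ++j) x[j] = X(i, j);
    const int lo = ptr[i], hi = ptr[i + 1];
    double ll = subject_ll(m, &ages[lo], &otype[lo], &ostate[lo], hi - lo, x, step);
    ll *= w[i];
    if (by_subject) (*by_subject)[i] = ll;
    if (ll == NEG_INF) {
      if (!by_subject) return NEG_INF;
      tot = NEG_INF;
    } else if (tot != NEG_INF) {
      tot += ll;
    }
  }
  return tot;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_interval_p(List model, double a0, double a1,
                         arma::rowvec x, double step) {
  Model m = build_model(model);
  return interval_p(m, a0, a1, x, step);
}

// [[Rcpp::export]]
arma::mat cpp_qmat(List model, double age, arma::rowvec x) {
  Model m = build_model(model);
  return qmat(m, age, x);
}

// [[Rcpp::export]]
double cpp_loglik(arma::vec theta, List model, List data, double step) {
  Model m = build_model(model);
  set_theta(m, theta);
  return total_ll(m, data, step);
}

// [[Rcpp::export]]
arma::vec cpp_loglik_by_subject(arma::vec theta, List model, List data,
                                double step) {
  Model m = build_model(model);
  set_theta(m, theta);
  const IntegerVector ptr = data["ptr"];
  arma::vec out(ptr.size() - 1, arma::fill::zeros);
  total_ll(m, data, step, &out);
  return out;
}

// Finite-difference gradient over the free parameters (1-based indices into theta).
// Forward differences by default (p + 1 evaluations); central on request.
// [[Rcpp::export]]
arma::vec cpp_loglik_grad(arma::vec theta, List model, List data, double step,
                          arma::uvec free_idx, bool central) {
  Model m = build_model(model);
  arma::vec g(free_idx.n_elem, arma::fill::zeros);
  double f0 = NA_REAL;
  if (!central) {
    set_theta(m, theta);
    f0 = total_ll(m, data, step);
    if (!R_finite(f0)) { g.fill(NA_REAL); return g; }
  }
  for (arma::uword k = 0; k < free_idx.n_elem; ++k) {
    const arma::uword j = free_idx[k] - 1;
    const double h = 1e-6 * (1.0 + std::abs(theta[j]));
    arma::vec th = theta;
    th[j] += h;
    set_theta(m, th);
    const double fp = total_ll(m, data, step);
    double fm = f0, denom = h;
    if (central) {
      th[j] = theta[j] - h;
      set_theta(m, th);
      fm = total_ll(m, data, step);
      denom = 2.0 * h;
    }
    g[k] = (R_finite(fp) && R_finite(fm)) ? (fp - fm) / denom : NA_REAL;
  }
  return g;
}
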