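// Continuous-time Markov chain numerics: interval transition probabilities,
// scaled forward recursion, forward-filtering backward-sampling, and exact
// endpoint-conditioned path simulation (rejection sampling with a
// uniformization fallback).  States are 0-based here; R wrappers are 1-based.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Provider for P(dt) = exp(Q dt).  A spectral decomposition of Q is attempted
// once; if Q is (numerically) defective we fall back to scaling-and-squaring
// per interval.  Results are cached per rounded gap length (1e-12 grid).
class TransProb {
public:
  arma::mat Q;
  int K;
  bool spectral_ok;
  arma::cx_vec eval;
  arma::cx_mat U, Uinv;
  std::map<long long, arma::mat> cache;

  explicit TransProb(const arma::mat& Q_) : Q(Q_), K(Q_.n_rows) {
    spectral_ok = false;
    if (K > 1) {
      arma::cx_vec ev;
      arma::cx_mat V;
      bool ok = arma::eig_gen(ev, V, arma::cx_mat(Q, arma::zeros(K, K)));
      if (ok) {
        arma::cx_mat Vi;
        if (arma::inv(Vi, V)) {
          arma::mat rec = arma::real(V * arma::diagmat(ev) * Vi);
          double rel = arma::norm(rec - Q, "fro") /
                       std::max(1.0, arma::norm(Q, "fro"));
          if (rel < 1e-10) {
            eval = ev; U = V; Uinv = Vi; spectral_ok = true;
          }
        }
      }
    }
  }

  arma::mat compute(double dt) const {
    if (K == 1) return arma::ones(1, 1);
    arma::mat P;
    if (spectral_ok) {
      arma::cx_vec e = arma::exp(eval * dt);
      P = arma::real(U * arma::diagmat(e) * Uinv);
    } else {
      P = arma::expmat(Q * dt);
    }
    // clamp rounding noise and renormalise rows
    P.clamp(0.0, arma::datum::inf);
    for (int i = 0; i < K; ++i) {
      double s = arma::accu(P.row(i));
      if (s > 0) P.row(i) /= s;
    }
    return P;
  }

  const arma::mat& get(double dt) {
    long long key = llround(dt * 1e12);
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    auto ins = cache.emplace(key, compute(dt));
    return ins.first->second;
  }
};

// [[Rcpp::export]]
arma::mat cpp_trans_prob(const arma::mat& Q, double dt) {
  TransProb tp(Q);
  return tp.compute(dt);
}

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& A) {
  return arma::expmat(A);
}

// ---------------------------------------------------------------------------
// Forward marginal likelihood, per subject, with per-step scaling.
// logf: (total observations) x K emission log-densities, subjects stacked;
// times: stacked observation times; offsets: length N+1, 0-based row offsets.
// ---------------------------------------------------------------------------

static double forward_one(const arma::vec& pi, TransProb& tp,
                          const arma::mat& logf, const arma::vec& times,
                          int lo, int hi) {
  const int K = pi.n_elem;
  arma::rowvec a(K);
  double acc = 0.0;
  arma::rowvec lf = logf.row(lo);
  double m = lf.max();
  for (int k = 0; k < K; ++k) a(k) = pi(k) * std::exp(lf(k) - m);
  double s = arma::accu(a);
  if (!(s > 0) || !std::isfinite(s)) return -arma::datum::inf;
  acc += m + std::log(s);
  a /= s;
  for (int t = lo + 1; t < hi; ++t) {
    double dt = times(t) - times(t - 1);
    a = a * tp.get(dt);
    lf = logf.row(t);
    m = lf.max();
    for (int k = 0; k < K; ++k) a(k) *= std::exp(lf(k) - m);
    s = arma::accu(a);
    if (!(s > 0) || !std::isfinite(s)) return -arma::datum::inf;
    acc += m + std::log(s);
    a /= s;
  }
  return acc;
}

// [[Rcpp::export]]
arma::vec cpp_forward_loglik(const arma::vec& pi, const arma::mat& Q,
                             const arma::mat& logf, const arma::vec& times,
                             const arma::ivec& offsets) {
  TransProb tp(Q);
  const int N = offsets.n_elem - 1;
  arma::vec out(N);
  for (int n = 0; n < N; ++n)
    out(n) = forward_one(pi, tp, logf, times, offsets(n), offsets(n + 1));
  return out;
}

// ---------------------------------------------------------------------------
// Forward-filtering backward-sampling of the discrete skeleton at the
// observation times of one subject.  Returns 0-based states.
// ---------------------------------------------------------------------------

static int sample_index(const arma::vec& w) {
  double tot = arma::accu(w);
  double u = unif_rand() * tot;
  double c = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    c += w(k);
    if (u <= c) return (int)k;
  }
  return (int)w.n_elem - 1;
}

static arma::ivec ffbs_one(const arma::vec& pi, TransProb& tp,
                           const arma::mat& logf, const arma::vec& times,
                           int lo, int hi, bool& ok) {
  const int K = pi.n_elem;
  const int T = hi - lo;
  arma::mat alpha(T, K);
  arma::rowvec a(K);
  arma::rowvec lf = logf.row(lo);
  double m = lf.max();
  for (int k = 0; k < K; ++k) a(k) = pi(k) * std::exp(lf(k) - m);
  double s = arma::accu(a);
  if (!(s > 0) || !std::isfinite(s)) { ok = false; return arma::ivec(); }
  alpha.row(0) = a / s;
  for (int t = 1; t < T; ++t) {
    double dt = times(lo + t) - times(lo + t - 1);
    a = alpha.row(t - 1) * tp.get(dt);
    lf = logf.row(lo + t);
    m = lf.max();
    for (int k = 0; k < K; ++k) a(k) *= std::exp(lf(k) - m);
    s = arma::accu(a);
    if (!(s > 0) || !std::isfinite(s)) { ok = false; return arma::ivec(); }
    alpha.row(t) = a / s;
  }
  arma::ivec states(T);
  states(T - 1) = sample_index(alpha.row(T - 1).t());
  for (int t = T - 2; t >= 0; --t) {
    double dt = times(lo + t + 1) - times(lo + t);
    const arma::mat& P = tp.get(dt);
    arma::vec w(K);
    for (int k = 0; k < K; ++k) w(k) = alpha(t, k) * P(k, states(t + 1));
    states(t) = sample_index(w);
  }
  ok = true;
  return states;
}

// ---------------------------------------------------------------------------
// Path simulation.
// ---------------------------------------------------------------------------

struct Path {
  std::vector<int> states;     // 0-based
  std::vector<double> times;   // entry times, first = 0
};

// Gillespie simulation from a fixed initial state over [0, horizon].
static Path simulate_from(const arma::mat& Q, int a, double horizon) {
  Path p;
  int cur = a;
  double t = 0.0;
  p.states.push_back(cur);
  p.times.push_back(0.0);
  const int K = Q.n_rows;
  while (true) {
    double rate = -Q(cur, cur);
    if (rate <= 0) break;
    t += exp_rand() / rate;
    if (t >= horizon) break;
    arma::vec w(K, arma::fill::zeros);
    for (int j = 0; j < K; ++j) if (j != cur) w(j) = Q(cur, j);
    cur = sample_index(w);
    p.states.push_back(cur);
    p.times.push_back(t);
  }
  return p;
}

// [[Rcpp::export]]
List cpp_simulate_ctmc(const arma::mat& Q, const arma::vec& pi,
                       double horizon) {
  int a = sample_index(pi);
  Path p = simulate_from(Q, a, horizon);
  return List::create(_["states"] = IntegerVector(p.states.begin(), p.states.end()),
                      _["times"] = NumericVector(p.times.begin(), p.times.end()));
}

// Exact endpoint-conditioned draw via uniformization (always applicable).
static Path conditioned_uniformization(const arma::mat& Q, int a, int b,
                                       double dt, const arma::mat& P) {
  const int K = Q.n_rows;
  double R = (-Q.diag()).max();
  Path p;
  if (R <= 0) {  // no movement possible
    p.states.push_back(a);
    p.times.push_back(0.0);
    return p;
  }
  arma::mat Pu = arma::eye(K, K) + Q / R;
  double pab = P(a, b);
  if (!(pab > 0)) stop("endpoint pair (%d -> %d) has zero probability", a + 1, b + 1);
  // sample the number of uniformized jumps n | a, b, dt
  double mu = R * dt;
  std::vector<arma::mat> pow;  // Pu^0 .. Pu^n
  pow.push_back(arma::eye(K, K));
  double u = unif_rand() * pab;
  double cum = 0.0;
  int n = -1;
  const int ncap = (int)std::ceil(mu + 12.0 * std::sqrt(mu + 1.0)) + 50;
  for (int j = 0; j <= ncap; ++j) {
    if (j > 0) pow.push_back(pow[j - 1] * Pu);
    cum += R::dpois(j, mu, 0) * pow[j](a, b);
    if (u <= cum) { n = j; break; }
  }
  if (n < 0) n = ncap;  // truncation tail, negligible mass
  // skeleton states V_0 = a, ..., V_n = b
  std::vector<int> V(n + 1);
  V[0] = a; V[n] = b;
  for (int j = 1; j < n; ++j) {
    arma::vec w(K);
    for (int v = 0; v < K; ++v) w(v) = Pu(V[j - 1], v) * pow[n - j](v, b);
    V[j] = sample_index(w);
  }
  // jump times: order statistics of n uniforms on (0, dt)
  arma::vec tt(n > 0 ? n : 1);
  if (n > 0) {
    for (int j = 0; j < n; ++j) tt(j) = unif_rand() * dt;
    tt = arma::sort(tt.head(n));
  }
  p.states.push_back(a);
  p.times.push_back(0.0);
  int cur = a;
  for (int j = 1; j <= n; ++j) {
    if (V[j] != cur) {
      cur = V[j];
      p.states.push_back(cur);
      p.times.push_back(tt(j - 1));
    }
  }
  return p;
}

// Hobolth-Stone rejection samplers with bounded attempts, then fall back to
// uniformization; every route is an exact draw from the conditioned law.
static Path conditioned_path(const arma::mat& Q, int a, int b, double dt,
                             const arma::mat& P, int max_attempts) {
  const int K = Q.n_rows;
  if (K == 1 || dt <= 0.0) {
    Path p; p.states.push_back(a); p.times.push_back(0.0); return p;
  }
  double qa = -Q(a, a);
  if (a == b) {
    for (int it = 0; it < max_attempts; ++it) {  // direct rejection
      Path p = simulate_from(Q, a, dt);
      if (p.states.back() == b) return p;
    }
  } else {
    if (qa <= 0) stop("state %d is absorbing yet an exit is required", a + 1);
    double pstay = std::exp(-qa * dt);
    for (int it = 0; it < max_attempts; ++it) {  // modified rejection
      // first jump time, conditioned on at least one jump in (0, dt)
      double u = unif_rand();
      double t1 = -std::log(1.0 - u * (1.0 - pstay)) / qa;
      arma::vec w(K, arma::fill::zeros);
      for (int j = 0; j < K; ++j) if (j != a) w(j) = Q(a, j);
      int s1 = sample_index(w);
      Path tail = simulate_from(Q, s1, dt - t1);
      if (tail.states.back() != b) continue;
      Path p;
      p.states.push_back(a);
      p.times.push_back(0.0);
      for (size_t j = 0; j < tail.states.size(); ++j) {
        p.states.push_back(tail.states[j]);
        p.times.push_back(t1 + tail.times[j]);
      }
      return p;
    }
  }
  return conditioned_uniformization(Q, a, b, dt, P);
}

// [[Rcpp::export]]
List cpp_sample_conditioned_path(const arma::mat& Q, int a, int b, double dt,
                                 int max_attempts) {
  TransProb tp(Q);
  arma::mat P = tp.compute(dt);
  if (!(P(a, b) > 0))
    stop("endpoint pair (%d -> %d) has zero probability over dt", a + 1, b + 1);
  Path p = conditioned_path(Q, a, b, dt, P, max_attempts);
  return List::create(_["states"] = IntegerVector(p.states.begin(), p.states.end()),
                      _["times"] = NumericVector(p.times.begin(), p.times.end()));
}

// ---------------------------------------------------------------------------
// Batched latent-path imputation: FFBS skeleton at observation times, then
// endpoint-conditioned fill of every inter-observation interval.  Returns the
// CTMC sufficient statistics and (optionally) the full paths.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_impute_paths(const arma::vec& pi, const arma::mat& Q,
                      const arma::mat& logf, const arma::vec& times,
                      const arma::ivec& offsets, bool keep_paths,
                      int max_attempts) {
  TransProb tp(Q);
  const int N = offsets.n_elem - 1;
  const int K = pi.n_elem;
  arma::mat ntrans(K, K, arma::fill::zeros);
  arma::vec dwell(K, arma::fill::zeros);
  arma::ivec init_counts(K, arma::fill::zeros);
  IntegerVector skeleton(logf.n_rows);
  List paths(keep_paths ? N : 0);

  for (int n = 0; n < N; ++n) {
    int lo = offsets(n), hi = offsets(n + 1);
    bool ok = true;
    arma::ivec sk = ffbs_one(pi, tp, logf, times, lo, hi, ok);
    if (!ok)
      stop("forward filter underflow for subject %d", n + 1);
    for (int t = 0; t < hi - lo; ++t) skeleton[lo + t] = sk(t) + 1;
    init_counts(sk(0)) += 1;

    Path full;
    full.states.push_back(sk(0));
    full.times.push_back(0.0);
    for (int t = 1; t < hi - lo; ++t) {
      double t0 = times(lo + t - 1), t1 = times(lo + t);
      double dt = t1 - t0;
      if (dt <= 0) continue;
      const arma::mat& P = tp.get(dt);
      if (!(P(sk(t - 1), sk(t)) > 0))
        stop("infeasible skeleton segment for subject %d", n + 1);
      Path seg = conditioned_path(Q, sk(t - 1), sk(t), dt, P, max_attempts);
      for (size_t j = 1; j < seg.states.size(); ++j) {
        full.states.push_back(seg.states[j]);
        full.times.push_back(t0 + seg.times[j]);
      }
    }
    double horizon = times(hi - 1);
    for (size_t j = 0; j < full.states.size(); ++j) {
      double tend = (j + 1 < full.states.size()) ? full.times[j + 1] : horizon;
      dwell(full.states[j]) += tend - full.times[j];
      if (j + 1 < full.states.size())
        ntrans(full.states[j], full.states[j + 1]) += 1.0;
    }
    if (keep_paths) {
      paths[n] = List::create(
        _["states"] = IntegerVector(full.states.begin(), full.states.end()),
        _["times"] = NumericVector(full.times.begin(), full.times.end()));
    }
  }
  List out = List::create(_["skeleton"] = skeleton,
                          _["ntrans"] = ntrans,
                          _["dwell"] = dwell,
                          _["init_counts"] = init_counts);
  if (keep_paths) out["paths"] = paths;
  return out;
}
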