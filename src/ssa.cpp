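#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Propensity kinds understood by the engine. Kinds 1-3 are evaluated in
// compiled code; kind 4 calls back into R (correct but slow, for custom
// state-dependent laws).
//   1 mass action:        rate * prod_i choose(x_i, order_i)
//   2 linear-weighted:    rate * prod_i choose(x_i, order_i) * sum_j w_j x_j
//   3 chain-equilibrium:  rate * x_target * sum_i w_i pi_i(x_driver)
//                         with pi ~ truncated geometric, ratio x_driver/kp
//   4 R function of the state vector
struct Prop {
  int kind;
  double rate;
  std::vector<int> ridx;      // reactant indices (0-based)
  std::vector<int> rord;      // reactant orders
  std::vector<double> w;      // weights (kinds 2, 3)
  int target, driver;         // kind 3
  double kp;                  // kind 3
  SEXP rfun = R_NilValue;
};

static double comb(double x, int k) {
  // number of distinct k-subsets of x molecules (Gillespie's h term)
  double h = 1.0;
  for (int i = 0; i < k; ++i) h *= (x - i) / (i + 1.0);
  return h > 0.0 ? h : 0.0;
}

static double chain_weight(double c, double kp, const std::vector<double>& w) {
  // sum_i w_i pi_i with pi_i proportional to (c/kp)^i, i = 0..L-1
  const int L = (int)w.size();
  double r = c / kp;
  long double num = 0.0L, den = 0.0L, ri = 1.0L;
  for (int i = 0; i < L; ++i) { num += (long double)w[i] * ri; den += ri; ri *= r; }
  return (double)(num / den);
}

static double eval_prop(const Prop& p, const std::vector<double>& x,
                        NumericVector& xbuf, int j) {
  double a;
  switch (p.kind) {
  case 1: {
    a = p.rate;
    for (size_t i = 0; i < p.ridx.size(); ++i) a *= comb(x[p.ridx[i]], p.rord[i]);
    break;
  }
  case 2: {
    a = p.rate;
    for (size_t i = 0; i < p.ridx.size(); ++i) a *= comb(x[p.ridx[i]], p.rord[i]);
    double s = 0.0;
    for (size_t i = 0; i < p.w.size(); ++i) s += p.w[i] * x[i];
    a *= s;
    break;
  }
  case 3: {
    double xt = x[p.target];
    if (xt <= 0.0) { a = 0.0; break; }
    a = p.rate * xt * chain_weight(x[p.driver], p.kp, p.w);
    break;
  }
  default: {
    for (size_t i = 0; i < x.size(); ++i) xbuf[i] = x[i];
    Function f(p.rfun);
    a = as<double>(f(xbuf));
    break;
  }
  }
  if (a < 0.0 || !std::isfinite(a))
    stop("negative or non-finite propensity (%g) for reaction %d", a, j + 1);
  return a;
}

// [[Rcpp::export]]
List ssa_run_cpp(List props, IntegerMatrix nu, NumericVector init,
                 double t_end, double burn_in,
                 int record_mode,     // 0 none, 1 every jump, 2 thinned grid
                 double thin_dt, double max_records,
                 int stop_species,    // 1-based; 0 = none / use stop_fun
                 double stop_value, int stop_dir,   // +1: x >= v, -1: x <= v
                 Nullable<Function> stop_fun,
                 bool track_occupancy) {
  const int N = nu.nrow(), M = nu.ncol();
  std::vector<Prop> P((size_t)M);
  for (int j = 0; j < M; ++j) {
    List pj = props[j];
    Prop& p = P[j];
    p.kind = as<int>(pj["kind"]);
    p.rate = pj.containsElementNamed("rate") ? as<double>(pj["rate"]) : 0.0;
    if (pj.containsElementNamed("ridx")) {
      IntegerVector ri = pj["ridx"], ro = pj["rord"];
      for (int i = 0; i < ri.size(); ++i) {
        p.ridx.push_back(ri[i] - 1);
        p.rord.push_back(ro[i]);
      }
    }
    if (pj.containsElementNamed("w")) {
      NumericVector w = pj["w"];
      p.w.assign(w.begin(), w.end());
    }
    if (p.kind == 3) {
      p.target = as<int>(pj["target"]) - 1;
      p.driver = as<int>(pj["driver"]) - 1;
      p.kp = as<double>(pj["kp"]);
    }
    if (p.kind == 4) p.rfun = pj["fun"];
  }

  bool use_sfun = stop_fun.isNotNull();
  SEXP sfun_sexp = use_sfun ? (SEXP)stop_fun.get() : R_NilValue;

  std::vector<double> x(init.begin(), init.end());
  NumericVector xbuf(N);
  std::vector<double> a((size_t)M);

  std::vector<double> rec_t;
  std::vector<double> rec_x;       // row-major N per record
  auto record_state = [&](double t) {
    rec_t.push_back(t);
    for (int i = 0; i < N; ++i) rec_x.push_back(x[i]);
  };

  // occupancy[s][v] = time spent with x[s] == v after burn_in
  std::vector< std::vector<double> > occ;
  if (track_occupancy) occ.assign((size_t)N, std::vector<double>());
  auto add_occ = [&](double from, double to) {
    if (!track_occupancy) return;
    double lo = from > burn_in ? from : burn_in;
    if (to <= lo) return;
    double dt = to - lo;
    for (int s = 0; s < N; ++s) {
      size_t v = (size_t)(x[s] + 0.5);
      if (occ[s].size() <= v) occ[s].resize(v + 1, 0.0);
      occ[s][v] += dt;
    }
  };

  auto stopped_now = [&]() -> bool {
    if (stop_species > 0)
      return stop_dir >= 0 ? x[stop_species - 1] >= stop_value
                           : x[stop_species - 1] <= stop_value;
    if (use_sfun) {
      for (int i = 0; i < N; ++i) xbuf[i] = x[i];
      Function f(sfun_sexp);
      return as<bool>(f(xbuf));
    }
    return false;
  };

  RNGScope rng;
  double t = 0.0, next_grid = thin_dt;
  bool stopped = false;
  double nsteps = 0.0;
  if (record_mode == 1) record_state(0.0);
  double stop_time = NA_REAL;

  if (stopped_now()) {
    stopped = true;
    stop_time = 0.0;
  } else {
    for (;;) {
      double a0 = 0.0;
      for (int j = 0; j < M; ++j) { a[j] = eval_prop(P[j], x, xbuf, j); a0 += a[j]; }
      if (a0 <= 0.0) break;                      // frozen state
      double r1 = unif_rand();
      double tau = std::log(1.0 / r1) / a0;
      double r2 = unif_rand();
      double thresh = r2 * a0, cum = 0.0;
      int j = M - 1;                             // strict inequality; last index
      for (int l = 0; l < M; ++l) {              // catches the measure-zero tie
        cum += a[l];
        if (cum > thresh) { j = l; break; }
      }
      double t_new = t + tau;
      if (t_new >= t_end) {                      // no firing inside horizon
        add_occ(t, t_end);
        if (record_mode == 2)
          while (next_grid <= t_end + 1e-12 * t_end) { record_state(next_grid); next_grid += thin_dt; }
        t = t_end;
        break;
      }
      add_occ(t, t_new);
      if (record_mode == 2)
        while (next_grid <= t_new) { record_state(next_grid); next_grid += thin_dt; }
      for (int i = 0; i < N; ++i) {
        x[i] += nu(i, j);
        if (x[i] < 0.0)
          stop("reaction %d drove species %d negative", j + 1, i + 1);
      }
      t = t_new;
      nsteps += 1.0;
      if (record_mode == 1) {
        if (rec_t.size() >= (size_t)max_records)
          stop("trajectory exceeds %g recorded jumps; use record = \"thin\" or \"none\"",
               max_records);
        record_state(t);
      }
      if (nsteps >= 1e12) stop("step budget exhausted");
      if ((((long long)nsteps) & 0xFFFFF) == 0) checkUserInterrupt();
      if (stopped_now()) { stopped = true; stop_time = t; break; }
    }
  }
  double final_time = stopped ? stop_time : (t < t_end ? t_end : t);
  if (!stopped && t < t_end) {
    // a0 hit zero before the horizon: state frozen until t_end
    add_occ(t, t_end);
    if (record_mode == 2)
      while (next_grid <= t_end + 1e-12 * t_end) { record_state(next_grid); next_grid += thin_dt; }
    final_time = t_end;
  }

  NumericMatrix states((int)rec_t.size(), N);
  for (size_t r = 0; r < rec_t.size(); ++r)
    for (int i = 0; i < N; ++i) states((int)r, i) = rec_x[r * N + i];

  List occ_out(N);
  if (track_occupancy)
    for (int s = 0; s < N; ++s) occ_out[s] = NumericVector(occ[s].begin(), occ[s].end());

  NumericVector xfin(N);
  for (int i = 0; i < N; ++i) xfin[i] = x[i];

  return List::create(
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["states"] = states,
    _["final_state"] = xfin,
    _["final_time"] = final_time,
    _["stopped"] = stopped,
    _["stop_time"] = stop_time,
    _["nsteps"] = nsteps,
    _["occupancy"] = occ_out);
}
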