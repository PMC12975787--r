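#include <Rcpp.h>
using namespace Rcpp;

// The compiled core of the continuous-time Markov chain simulator.
//
// A model is handed over from R as a flat list of arrays describing every
// event channel (see build_event_set()).  Four rate formulas cover the whole
// event set:
//   1 linear      a = c * x[src]                 (development, aging, death,
//                                                 emigration, emergence)
//   2 constant    a = c                          (immigration)
//   3 birth       a = c * x[src] * max(0, 1 - Itot/C)
//   4 mating      a = c * x[src] * g_m * sum(x[grp]) / sum_s g_s * males_s
// Each event changes at most two compartments by +-1 (d2i = -1 when unused).
// All randomness is drawn from R's RNG so set.seed() controls everything.

struct CModel {
  IntegerVector cat, src, d1i, d1v, d2i, d2v, grp_lo, grp_hi;
  NumericVector cc, gma;
  int imm_lo, imm_hi;
  double capacity;
  IntegerVector male_lo, male_hi;
  NumericVector male_gamma;
  int ne;
};

static CModel unpack(const List& model) {
  CModel m;
  m.cat = model["cat"];
  m.src = model["src"];
  m.d1i = model["d1i"];
  m.d1v = model["d1v"];
  m.d2i = model["d2i"];
  m.d2v = model["d2v"];
  m.grp_lo = model["grp_lo"];
  m.grp_hi = model["grp_hi"];
  m.cc = model["cc"];
  m.gma = model["gma"];
  m.imm_lo = as<int>(model["imm_lo"]);
  m.imm_hi = as<int>(model["imm_hi"]);
  m.capacity = as<double>(model["capacity"]);
  m.male_lo = model["male_lo"];
  m.male_hi = model["male_hi"];
  m.male_gamma = model["male_gamma"];
  m.ne = m.cat.size();
  return m;
}

static void comp_props(const NumericVector& x, const CModel& m, NumericVector& a) {
  double itot = 0.0;
  if (m.imm_lo >= 0)
    for (int i = m.imm_lo; i <= m.imm_hi; ++i) itot += x[i];
  double dens = 1.0 - itot / m.capacity;
  if (dens < 0) dens = 0;
  double wm = 0.0;
  for (int s = 0; s < m.male_lo.size(); ++s)
    for (int i = m.male_lo[s]; i <= m.male_hi[s]; ++i)
      wm += m.male_gamma[s] * x[i];
  for (int e = 0; e < m.ne; ++e) {
    double r;
    switch (m.cat[e]) {
    case 1: r = m.cc[e] * x[m.src[e]]; break;
    case 2: r = m.cc[e]; break;
    case 3: r = m.cc[e] * x[m.src[e]] * dens; break;
    case 4: {
      if (wm <= 0) { r = 0.0; break; }
      double g = 0.0;
      for (int i = m.grp_lo[e]; i <= m.grp_hi[e]; ++i) g += x[i];
      r = m.cc[e] * x[m.src[e]] * m.gma[e] * g / wm;
      break;
    }
    default: r = 0.0;
    }
    if (!R_finite(r) || r < 0)
      stop("invalid propensity (event %d, value %f)", e + 1, r);
    a[e] = r;
  }
}

static void apply_delta(NumericVector& x, const CModel& m, int e) {
  x[m.d1i[e]] += m.d1v[e];
  if (m.d2i[e] >= 0) x[m.d2i[e]] += m.d2v[e];
}

// Exact (direct method) advance of x from t0 to t1; returns nothing, x is
// modified in place.  The exponential clock is redrawn after every boundary,
// which is exact by memorylessness.
static void ssa_advance(NumericVector& x, const CModel& m, double t0, double t1,
                        NumericVector& a) {
  double t = t0;
  while (true) {
    comp_props(x, m, a);
    double a0 = 0.0;
    for (int e = 0; e < m.ne; ++e) a0 += a[e];
    if (a0 <= 0) return;
    double dt = R::exp_rand() / a0;
    if (t + dt >= t1) return;
    t += dt;
    double u = unif_rand() * a0;
    int e = 0;
    double cum = a[0];
    while (cum < u && e < m.ne - 1) cum += a[++e];
    apply_delta(x, m, e);
  }
}

// Tau-leap advance with a non-negativity safeguard: a leap whose Poisson
// counts would drive any compartment negative is rolled back and re-simulated
// exactly over the same sub-interval.
static void tau_advance(NumericVector& x, const CModel& m, double t0, double t1,
                        double tau, NumericVector& a, NumericVector& xsave) {
  double t = t0;
  while (t < t1 - 1e-12) {
    double step = tau;
    if (t + step > t1) step = t1 - t;
    comp_props(x, m, a);
    for (int i = 0; i < x.size(); ++i) xsave[i] = x[i];
    bool neg = false;
    for (int e = 0; e < m.ne; ++e) {
      if (a[e] <= 0) continue;
      int k = (int) R::rpois(a[e] * step);
      if (k > 0) {
        x[m.d1i[e]] += (double) k * m.d1v[e];
        if (m.d2i[e] >= 0) x[m.d2i[e]] += (double) k * m.d2v[e];
      }
    }
    for (int i = 0; i < x.size(); ++i)
      if (x[i] < 0) { neg = true; break; }
    if (neg) {
      for (int i = 0; i < x.size(); ++i) x[i] = xsave[i];
      ssa_advance(x, m, t, t + step, a);
    }
    t += step;
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_propensities(NumericVector x, List model) {
  CModel m = unpack(model);
  NumericVector a(m.ne);
  comp_props(x, m, a);
  return a;
}

// Simulate from t0 to t1, recording the state at each time in rec_times
// (sorted, all in (t0, t1]).  method: 0 = exact SSA, 1 = tau-leap.
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, List model, double t0, double t1,
                  NumericVector rec_times, int method, double tau) {
  CModel m = unpack(model);
  NumericVector x = clone(x0);
  NumericVector a(m.ne), xsave(x.size());
  int nrec = rec_times.size();
  NumericMatrix rec(nrec, x.size());
  double t = t0;
  for (int r = 0; r < nrec; ++r) {
    double te = rec_times[r];
    if (te < t - 1e-12) stop("record times must be non-decreasing and > t0");
    if (te > t) {
      if (method == 0) ssa_advance(x, m, t, te, a);
      else tau_advance(x, m, t, te, tau, a, xsave);
      t = te;
    }
    for (int i = 0; i < x.size(); ++i) rec(r, i) = x[i];
  }
  if (t1 > t) {
    if (method == 0) ssa_advance(x, m, t, t1, a);
    else tau_advance(x, m, t, t1, tau, a, xsave);
  }
  return List::create(_["state"] = x, _["record"] = rec);
}
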