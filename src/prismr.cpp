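// Simulated-annealing optimisation of a binding-site profile against a
// target contact map, under the mean-field forward model
//   M_uv = min(1, B_uv + beta * sum_t p[t,u] p[t,v]),  B_uv = (1+|u-v|)^-gamma
// with cost = sum_{u<v} (M_uv - T_uv)^2 + lambda * (total sites).
// Move set: add/remove a site, relocate a site within its type, switch the
// type of a site.  Metropolis acceptance; geometric cooling.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SaRng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> unif;
  explicit SaRng(uint64_t seed) : gen(seed), unif(0.0, 1.0) {}
  double runif() { return unif(gen); }
  int rint(int n) {
    std::uniform_int_distribution<int> d(0, n - 1);
    return d(gen);
  }
};

struct SaState {
  int nTypes, n, cap;
  double beta, lambda;
  std::vector<int> prof;      // nTypes x n, column-major by bead
  std::vector<double> E;      // n x n co-occupancy
  std::vector<double> Bs;     // background by separation
  const double *T;            // target, n x n
  double sse;
  int totalSites;

  inline int &P(int t, int u) { return prof[t + nTypes * u]; }
  inline double model(int u, int v) const {
    double m = Bs[std::abs(u - v)] + beta * E[u + n * v];
    return m > 1.0 ? 1.0 : m;
  }

  void initE() {
    E.assign(static_cast<size_t>(n) * n, 0.0);
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v) {
        double e = 0.0;
        for (int t = 0; t < nTypes; ++t)
          e += prof[t + nTypes * u] * static_cast<double>(prof[t + nTypes * v]);
        E[u + n * v] = e;
      }
    sse = 0.0;
    totalSites = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v) {
        double d = model(u, v) - T[u + n * v];
        sse += d * d;
      }
    for (size_t k = 0; k < prof.size(); ++k) totalSites += prof[k];
  }

  // SSE change from adding delta (+1/-1) to p[t,u]; does not apply
  double deltaSSE(int t, int u, int delta) const {
    double dsse = 0.0;
    int pu = prof[t + nTypes * u];
    for (int v = 0; v < n; ++v) {
      if (v == u) continue;
      int pv = prof[t + nTypes * v];
      double eOld = E[u + n * v];
      double eNew = eOld + delta * static_cast<double>(pv);
      double bb = Bs[std::abs(u - v)];
      double mOld = bb + beta * eOld; if (mOld > 1.0) mOld = 1.0;
      double mNew = bb + beta * eNew; if (mNew > 1.0) mNew = 1.0;
      double tv = T[u + n * v];
      dsse += (mNew - tv) * (mNew - tv) - (mOld - tv) * (mOld - tv);
    }
    (void)pu;
    return dsse;
  }

  void apply(int t, int u, int delta) {
    for (int v = 0; v < n; ++v) {
      if (v == u) continue;
      double d = delta * static_cast<double>(prof[t + nTypes * v]);
      E[u + n * v] += d;
      E[v + n * u] += d;
    }
    // diagonal co-occupancy (unused by the off-diagonal cost, kept coherent)
    int pu = prof[t + nTypes * u];
    E[u + n * u] += 2.0 * pu * delta + delta * delta;
    prof[t + nTypes * u] += delta;
    totalSites += delta;
  }

  double cost() const { return sse + lambda * totalSites; }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_sa_anneal")]]
List cpp_sa_anneal(NumericMatrix target, int nTypes, double lambda,
                   double beta, double gamma, double T0, double cooling,
                   int nTemps, int innerPerTemp, int cap, double pInit,
                   int seed) {
  int n = target.nrow();
  SaState st;
  st.nTypes = nTypes; st.n = n; st.cap = cap;
  st.beta = beta; st.lambda = lambda;
  st.T = target.begin();
  st.Bs.resize(n);
  for (int s = 0; s < n; ++s) st.Bs[s] = std::pow(1.0 + s, -gamma);
  SaRng rng(static_cast<uint64_t>(seed));
  st.prof.assign(static_cast<size_t>(nTypes) * n, 0);
  for (size_t k = 0; k < st.prof.size(); ++k)
    if (rng.runif() < pInit) st.prof[k] = 1;
  st.initE();

  std::vector<int> bestProf = st.prof;
  double bestCost = st.cost();
  NumericVector trace(nTemps);
  double temp = T0;
  for (int tk = 0; tk < nTemps; ++tk) {
    for (int it = 0; it < innerPerTemp; ++it) {
      int kind = rng.rint(3);
      double dCost = 0.0;
      int t1 = 0, u1 = 0, d1 = 0, t2 = 0, u2 = 0, d2 = 0;
      bool two = false, valid = false;
      if (kind == 0) {  // add or remove at a random slot
        t1 = rng.rint(nTypes); u1 = rng.rint(n);
        int p = st.P(t1, u1);
        d1 = (p > 0) ? -1 : (p < cap ? +1 : 0);
        if (d1 != 0) {
          dCost = st.deltaSSE(t1, u1, d1) + st.lambda * d1;
          valid = true;
        }
      } else {  // relocate (kind 1) or switch type (kind 2): need a site
        bool found = false;
        for (int tries = 0; tries < 64 && !found; ++tries) {
          t1 = rng.rint(nTypes); u1 = rng.rint(n);
          if (st.P(t1, u1) > 0) found = true;
        }
        if (found) {
          if (kind == 1) { t2 = t1; u2 = rng.rint(n); }
          else { t2 = rng.rint(nTypes); u2 = u1; }
          if (!(t2 == t1 && u2 == u1) && st.P(t2, u2) < cap) {
            d1 = -1; d2 = +1; two = true;
            dCost = st.deltaSSE(t1, u1, d1);
            st.apply(t1, u1, d1);
            dCost += st.deltaSSE(t2, u2, d2);
            st.apply(t2, u2, d2);
            valid = true;
          }
        }
      }
      if (!valid) continue;
      bool accept = dCost <= 0.0 || rng.runif() < std::exp(-dCost / temp);
      if (kind == 0) {
        if (accept) { st.apply(t1, u1, d1); st.sse += dCost - st.lambda * d1; }
      } else if (two) {
        if (accept) {
          st.sse += dCost;  // site count unchanged
        } else {
          st.apply(t2, u2, -d2);
          st.apply(t1, u1, -d1);
        }
      }
      if (accept && st.cost() < bestCost) {
        bestCost = st.cost();
        bestProf = st.prof;
      }
    }
    trace[tk] = st.cost();
    temp *= cooling;
  }

  // converged if the last tenth of the trace is flat (relative to its scale)
  bool converged = true;
  int tail = std::max(2, nTemps / 10);
  double first = trace[nTemps - tail], last = trace[nTemps - 1];
  if (first > 0 && (first - last) / (std::fabs(first) + 1e-12) > 0.01)
    converged = false;

  IntegerMatrix outProf(nTypes, n);
  for (int u = 0; u < n; ++u)
    for (int t = 0; t < nTypes; ++t) outProf(t, u) = bestProf[t + nTypes * u];
  return List::create(_["profile"] = outProf, _["cost"] = bestCost,
                      _["trace"] = trace, _["converged"] = converged);
}
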