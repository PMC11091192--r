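// Langevin bead-spring engine for a chromatin polymer plus diffusing binders
// in a periodic cubic box, with concurrent loop extrusion.
//
// Force field (dimensionless units, sigma = 1, m = 1, energies in kBT):
//   - purely repulsive truncated LJ (WCA) core between all particle pairs;
//   - truncated-and-shifted attractive LJ between binders and cognate beads,
//     strength eps(binder type, bead) in kBT, cutoff r_int, exactly zero at
//     and beyond the cutoff;
//   - FENE bonds between consecutive beads (K = 30 kBT/sigma^2, R0 = 1.6);
//   - harmonic extruder springs (K = 10 kBT/sigma^2, r_eq = 1.1) between the
//     current leg beads of each loop-extruding factor.
//
// Integration: BAOAB Langevin splitting.  With zeta = 0 the O-step is the
// identity and the scheme reduces exactly to velocity Verlet (NVE), which the
// energy-drift tests exploit.  Polymer coordinates are kept unwrapped;
// non-bonded interactions use the minimum-image convention, bonded terms act
// on the unwrapped (physical) coordinates.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double WCA_CUT2 = std::pow(2.0, 1.0 / 3.0);  // (2^{1/6})^2

// xoshiro256++ with splitmix64 seeding; polar-method Gaussians with a
// one-value cache.  Self-contained and deterministic across platforms.
struct Rng {
  uint64_t s[4];
  bool haveSpare;
  double spare;
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  explicit Rng(uint64_t seed) : haveSpare(false), spare(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (haveSpare) { haveSpare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    haveSpare = true;
    return u * f;
  }
  inline int rint(int n) {  // uniform on 0..n-1
    return static_cast<int>(
        (static_cast<unsigned __int128>(next()) *
         static_cast<unsigned __int128>(n)) >> 64);
  }
};

// truncated-shifted LJ pair energy (full LJ core + attraction), 0 at r>=rint
static inline double vlj(double r, double eps, double rint) {
  if (r >= rint) return 0.0;
  double s6 = std::pow(1.0 / r, 6), s12 = s6 * s6;
  double c6 = std::pow(1.0 / rint, 6), c12 = c6 * c6;
  return 4.0 * eps * (s12 - s6 - c12 + c6);
}

// ---------------------------------------------------------------------------
// Loop extrusion core (shared between the MD engine and standalone wrappers)
// ---------------------------------------------------------------------------

struct ExtrusionSystem {
  int nBeads;
  int nExtr;
  std::vector<int> legL, legR;          // current leg beads, legL < legR
  std::vector<char> haltL, haltR;       // permanent (anchor-engaged) halts
  std::vector<int> occ;                 // bead -> extruder index or -1
  // anchors: orientation per bead: 0 none, 1 forward (+ strand, blocks
  // leftward-travelling legs), 2 reverse (- strand, blocks rightward legs),
  // 3 bidirectional; probability per bead.
  std::vector<int> anchorOrient;
  std::vector<double> anchorProb;
  // engagement memory: per extruder, bead -> engaged?  Drawn once on the
  // first attempted step onto the anchor bead, kept until detachment.
  std::vector<std::map<int, char> > mem;
  double kOff;                          // detachment rate per update
  bool oneSided;                        // halted leg's partner keeps moving
  std::vector<double> loopLenAtDetach;  // beads extruded, recorded on detach

  void initOcc() {
    occ.assign(nBeads, -1);
    for (int e = 0; e < nExtr; ++e) {
      occ[legL[e]] = e;
      occ[legR[e]] = e;
    }
  }

  void seed(Rng &rng) {
    legL.assign(nExtr, 0); legR.assign(nExtr, 0);
    haltL.assign(nExtr, 0); haltR.assign(nExtr, 0);
    mem.assign(nExtr, std::map<int, char>());
    occ.assign(nBeads, -1);
    for (int e = 0; e < nExtr; ++e) placeRandom(e, rng);
  }

  void placeRandom(int e, Rng &rng) {
    for (int tries = 0; tries < 200 * nBeads; ++tries) {
      int k = rng.rint(nBeads - 1);
      if (occ[k] == -1 && occ[k + 1] == -1) {
        legL[e] = k; legR[e] = k + 1;
        occ[k] = e; occ[k + 1] = e;
        haltL[e] = 0; haltR[e] = 0;
        mem[e].clear();
        return;
      }
    }
    stop("could not place extruder: polymer too crowded");
  }

  // attempt one outward step of one leg; dir = -1 (left leg) or +1 (right)
  void stepLeg(int e, int dir, Rng &rng) {
    int cur = (dir < 0) ? legL[e] : legR[e];
    char &halt = (dir < 0) ? haltL[e] : haltR[e];
    if (halt) return;
    if (!oneSided) {  // both legs stop if the partner is anchor-halted
      char other = (dir < 0) ? haltR[e] : haltL[e];
      if (other) return;
    }
    int tgt = cur + dir;
    if (tgt < 0 || tgt >= nBeads) return;          // polymer end: leg waits
    if (occ[tgt] != -1) return;                    // another leg: no pass-through
    int orient = anchorOrient[tgt];
    bool opposes = (orient == 3) ||
                   (dir < 0 && orient == 1) ||     // forward blocks leftward
                   (dir > 0 && orient == 2);       // reverse blocks rightward
    bool engaged = false;
    if (opposes && anchorProb[tgt] > 0.0) {
      std::map<int, char>::iterator it = mem[e].find(tgt);
      if (it == mem[e].end()) {
        char draw = (rng.runif() < anchorProb[tgt]) ? 1 : 0;
        mem[e][tgt] = draw;
        engaged = draw != 0;
      } else {
        engaged = it->second != 0;
      }
    }
    occ[cur] = -1;
    occ[tgt] = e;
    if (dir < 0) legL[e] = tgt; else legR[e] = tgt;
    if (engaged) halt = 1;                          // sits on the anchor bead
  }

  // one extrusion update: randomized synchronous order, then detachment
  void update(Rng &rng, bool doMove = true) {
    if (doMove) {
      std::vector<int> order(nExtr);
      for (int i = 0; i < nExtr; ++i) order[i] = i;
      for (int i = nExtr - 1; i > 0; --i)
        std::swap(order[i], order[rng.rint(i + 1)]);
      for (int oi = 0; oi < nExtr; ++oi) {
        int e = order[oi];
        stepLeg(e, -1, rng);
        stepLeg(e, +1, rng);
      }
    }
    if (kOff > 0.0) {
      double pDet = 1.0 - std::exp(-kOff);
      for (int e = 0; e < nExtr; ++e) {
        if (rng.runif() < pDet) {
          loopLenAtDetach.push_back(static_cast<double>(legR[e] - legL[e] - 1));
          occ[legL[e]] = -1; occ[legR[e]] = -1;
          placeRandom(e, rng);
        }
      }
    }
  }
};

static ExtrusionSystem makeExtrusion(IntegerMatrix legs, LogicalMatrix halted,
                                     int nBeads, IntegerVector anchorOrient,
                                     NumericVector anchorProb, double kOff,
                                     bool oneSided) {
  ExtrusionSystem ex;
  ex.nBeads = nBeads;
  ex.nExtr = legs.nrow();
  ex.kOff = kOff;
  ex.oneSided = oneSided;
  ex.legL.resize(ex.nExtr); ex.legR.resize(ex.nExtr);
  ex.haltL.resize(ex.nExtr); ex.haltR.resize(ex.nExtr);
  ex.mem.assign(ex.nExtr, std::map<int, char>());
  for (int e = 0; e < ex.nExtr; ++e) {
    ex.legL[e] = legs(e, 0); ex.legR[e] = legs(e, 1);
    if (ex.legL[e] < 0 || ex.legR[e] >= nBeads || ex.legL[e] >= ex.legR[e])
      stop("invalid extruder legs");
    ex.haltL[e] = halted(e, 0) ? 1 : 0;
    ex.haltR[e] = halted(e, 1) ? 1 : 0;
  }
  ex.anchorOrient.assign(anchorOrient.begin(), anchorOrient.end());
  ex.anchorProb.assign(anchorProb.begin(), anchorProb.end());
  ex.initOcc();
  return ex;
}

// [[Rcpp::export(name = ".cpp_extrusion_update")]]
List cpp_extrusion_update(IntegerMatrix legs, LogicalMatrix halted, int nBeads,
                          IntegerVector anchorOrient, NumericVector anchorProb,
                          double kOff, bool oneSided, int nUpdates,
                          int seed, bool doMove) {
  ExtrusionSystem ex = makeExtrusion(legs, halted, nBeads, anchorOrient,
                                     anchorProb, kOff, oneSided);
  Rng rng(static_cast<uint64_t>(seed));
  for (int u = 0; u < nUpdates; ++u) ex.update(rng, doMove);
  IntegerMatrix outLegs(ex.nExtr, 2);
  LogicalMatrix outHalt(ex.nExtr, 2);
  for (int e = 0; e < ex.nExtr; ++e) {
    outLegs(e, 0) = ex.legL[e]; outLegs(e, 1) = ex.legR[e];
    outHalt(e, 0) = ex.haltL[e] != 0; outHalt(e, 1) = ex.haltR[e] != 0;
  }
  return List::create(_["legs"] = outLegs, _["halted"] = outHalt,
                      _["loop_lengths"] = wrap(ex.loopLenAtDetach));
}

// [[Rcpp::export(name = ".cpp_seed_extruders")]]
IntegerMatrix cpp_seed_extruders(int nExtruders, int nBeads, int seed) {
  ExtrusionSystem ex;
  ex.nBeads = nBeads;
  ex.nExtr = nExtruders;
  ex.kOff = 0.0;
  ex.oneSided = true;
  Rng rng(static_cast<uint64_t>(seed));
  ex.seed(rng);
  IntegerMatrix legs(nExtruders, 2);
  for (int e = 0; e < nExtruders; ++e) {
    legs(e, 0) = ex.legL[e]; legs(e, 1) = ex.legR[e];
  }
  return legs;
}

// ---------------------------------------------------------------------------
// MD engine
// ---------------------------------------------------------------------------

struct Engine {
  int nb, nm, n;                 // beads, binders, total
  double boxL, dt, zeta, temp;
  double R0, kFene, kSpring, rEq, rInt;
  std::vector<double> x, v, f;   // 3*n
  std::vector<int> binderType;   // nm
  // eps(binder type t, bead u) stored as epsPB[t + nTypes*u]
  std::vector<double> epsPB;
  int nTypes;
  double maxCut;                 // largest interaction cutoff
  // neighbour list (per-pair epsilon cached at build; 0 = repulsive core)
  double skin;
  std::vector<int> nbrI, nbrJ;
  std::vector<double> nbrEps;
  std::vector<double> x0;        // positions at last rebuild
  std::vector<double> w;         // wrapped coordinates (per-step cache)
  double maxBond2;               // diagnostics: max FENE bond length^2 seen

  inline double img(double d) const { return d - boxL * std::nearbyint(d / boxL); }

  // wrapped coordinates drift at most skin/2 outside the box between
  // rebuild-scale intervals, so one conditional correction suffices
  inline double imgw(double d) const {
    double h = 0.5 * boxL;
    if (d > h) d -= boxL; else if (d < -h) d += boxL;
    if (d > h) d -= boxL; else if (d < -h) d += boxL;
    return d;
  }

  void refreshWrapped() {
    w.resize(3 * n);
    for (int i = 0; i < 3 * n; ++i)
      w[i] = x[i] - boxL * std::floor(x[i] / boxL);
  }

  // epsilon for pair (i, j); > 0 only for binder-cognate-bead pairs
  inline double pairEps(int i, int j) const {
    if (i < nb && j >= nb) return epsPB[binderType[j - nb] + nTypes * i];
    if (j < nb && i >= nb) return epsPB[binderType[i - nb] + nTypes * j];
    return 0.0;
  }

  void addPair(int i, int j, double r2, double wcaList2, double attList2) {
    double eps = pairEps(i, j);
    if (r2 < (eps > 0.0 ? attList2 : wcaList2)) {
      nbrI.push_back(i); nbrJ.push_back(j); nbrEps.push_back(eps);
    }
  }

  std::vector<int> cellHead, cellNext;   // allocation-free linked cells

  void buildList() {
    nbrI.clear(); nbrJ.clear(); nbrEps.clear();
    refreshWrapped();
    double rl = maxCut + skin, rl2 = rl * rl;
    double wcaList2 = std::sqrt(WCA_CUT2) + skin;  wcaList2 *= wcaList2;
    double attList2 = rInt + skin;                 attList2 *= attList2;
    int nc = std::max(1, static_cast<int>(std::floor(boxL / rl)));
    double cw = boxL / nc;
    if (nc < 3) {
      // box too small for cells at this cutoff: all-pairs fallback
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = imgw(w[3 * i] - w[3 * j]);
          double dy = imgw(w[3 * i + 1] - w[3 * j + 1]);
          double dz = imgw(w[3 * i + 2] - w[3 * j + 2]);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rl2) addPair(i, j, r2, wcaList2, attList2);
        }
      x0 = x;
      return;
    }
    size_t ncells = static_cast<size_t>(nc) * nc * nc;
    cellHead.assign(ncells, -1);
    cellNext.resize(n);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      ci[i] = std::min(nc - 1, static_cast<int>(w[3 * i] / cw));
      cj[i] = std::min(nc - 1, static_cast<int>(w[3 * i + 1] / cw));
      ck[i] = std::min(nc - 1, static_cast<int>(w[3 * i + 2] / cw));
      size_t c = (static_cast<size_t>(ci[i]) * nc + cj[i]) * nc + ck[i];
      cellNext[i] = cellHead[c];
      cellHead[c] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int ca = (ci[i] + a + nc) % nc, cb = (cj[i] + b + nc) % nc,
                cc = (ck[i] + c + nc) % nc;
            size_t cell = (static_cast<size_t>(ca) * nc + cb) * nc + cc;
            for (int j = cellHead[cell]; j != -1; j = cellNext[j]) {
              if (j <= i) continue;
              double dx = imgw(w[3 * i] - w[3 * j]);
              double dy = imgw(w[3 * i + 1] - w[3 * j + 1]);
              double dz = imgw(w[3 * i + 2] - w[3 * j + 2]);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rl2) addPair(i, j, r2, wcaList2, attList2);
            }
          }
    }
    x0 = x;
  }

  bool needRebuild() const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - x0[3 * i], dy = x[3 * i + 1] - x0[3 * i + 1],
             dz = x[3 * i + 2] - x0[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // potential energy returned for diagnostics (only exact when wanted)
  // the wrapped cache w is advanced incrementally with the positions and
  // re-derived exactly at every list rebuild; between rebuilds it can
  // drift at most half a skin outside the box, which imgw() covers
  double forces(const ExtrusionSystem *ex, bool wantEnergy, double *energyOut) {
    std::fill(f.begin(), f.end(), 0.0);
    double pe = 0.0;
    double wcaCut2 = WCA_CUT2, rInt2 = rInt * rInt;
    for (size_t p = 0; p < nbrI.size(); ++p) {
      int i = nbrI[p], j = nbrJ[p];
      double dx = imgw(w[3 * i] - w[3 * j]);
      double dy = imgw(w[3 * i + 1] - w[3 * j + 1]);
      double dz = imgw(w[3 * i + 2] - w[3 * j + 2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      double eps = nbrEps[p];
      double fr = 0.0;  // dV/dr / r  (force = -fr * dvec)
      if (eps > 0.0) {
        if (r2 < rInt2) {
          double inv2 = 1.0 / r2, inv6 = inv2 * inv2 * inv2, inv12 = inv6 * inv6;
          fr = 4.0 * eps * (-12.0 * inv12 + 6.0 * inv6) * inv2;
          if (wantEnergy) pe += vlj(std::sqrt(r2), eps, rInt);
        }
      } else {
        if (r2 < wcaCut2) {
          double inv2 = 1.0 / r2, inv6 = inv2 * inv2 * inv2, inv12 = inv6 * inv6;
          fr = 4.0 * (-12.0 * inv12 + 6.0 * inv6) * inv2;
          if (wantEnergy) pe += 4.0 * (inv12 - inv6) + 1.0;
        }
      }
      // numerical safeguard: cap the pair force magnitude so that rare
      // core overshoots cannot destabilise the integration (the capped
      // region carries negligible Boltzmann weight at equilibrium)
      if (fr * fr * r2 > 1e6) {
        double scale = 1e3 / std::sqrt(fr * fr * r2);
        fr *= scale;
      }
      if (fr != 0.0) {
        f[3 * i] -= fr * dx; f[3 * i + 1] -= fr * dy; f[3 * i + 2] -= fr * dz;
        f[3 * j] += fr * dx; f[3 * j + 1] += fr * dy; f[3 * j + 2] += fr * dz;
      }
    }
    // FENE bonds on unwrapped coordinates
    double R02 = R0 * R0;
    for (int i = 0; i + 1 < nb; ++i) {
      double dx = x[3 * i] - x[3 * (i + 1)];
      double dy = x[3 * i + 1] - x[3 * (i + 1) + 1];
      double dz = x[3 * i + 2] - x[3 * (i + 1) + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > maxBond2) maxBond2 = r2;
      if (r2 >= R02)
        stop("FENE bond exceeded R0 (dt too large or forces diverged)");
      double fr = kFene / (1.0 - r2 / R02);  // dV/dr / r
      f[3 * i] -= fr * dx; f[3 * i + 1] -= fr * dy; f[3 * i + 2] -= fr * dz;
      f[3 * (i + 1)] += fr * dx; f[3 * (i + 1) + 1] += fr * dy; f[3 * (i + 1) + 2] += fr * dz;
      if (wantEnergy) pe += -0.5 * kFene * R02 * std::log(1.0 - r2 / R02);
    }
    // extruder springs on unwrapped coordinates
    if (ex) {
      for (int e = 0; e < ex->nExtr; ++e) {
        int i = ex->legL[e], j = ex->legR[e];
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > 1e-12) {
          double fr = kSpring * (r - rEq) / r;
          f[3 * i] -= fr * dx; f[3 * i + 1] -= fr * dy; f[3 * i + 2] -= fr * dz;
          f[3 * j] += fr * dx; f[3 * j + 1] += fr * dy; f[3 * j + 2] += fr * dz;
        }
        if (wantEnergy) pe += 0.5 * kSpring * (r - rEq) * (r - rEq);
      }
    }
    if (energyOut) *energyOut = pe;
    return pe;
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
    return ke;
  }
};

// [[Rcpp::export(name = ".cpp_run_engine")]]
List cpp_run_engine(NumericMatrix beadPos, NumericMatrix beadVel,
                    NumericMatrix binderPos, NumericMatrix binderVel,
                    IntegerVector binderTypeIdx, NumericMatrix epsMat,
                    double rInt, double boxL, double dt, double zeta,
                    double temp, int nSteps, int sampleEvery, int seed,
                    bool storeBinders,
                    IntegerMatrix legs, LogicalMatrix halted,
                    IntegerVector anchorOrient, NumericVector anchorProb,
                    double kOff, bool oneSided, int stepInterval,
                    double R0, double kFene, double kSpring, double rEq) {
  Engine en;
  en.nb = beadPos.nrow();
  en.nm = binderPos.nrow();
  en.n = en.nb + en.nm;
  en.boxL = boxL; en.dt = dt; en.zeta = zeta; en.temp = temp;
  en.R0 = R0; en.kFene = kFene; en.kSpring = kSpring; en.rEq = rEq;
  en.rInt = rInt;
  en.nTypes = epsMat.nrow();
  en.maxBond2 = 0.0;
  if (epsMat.ncol() != en.nb && en.nb > 0)
    stop("epsMat must have one column per bead");
  en.epsPB.assign(epsMat.begin(), epsMat.end());
  en.binderType.assign(binderTypeIdx.begin(), binderTypeIdx.end());
  en.x.resize(3 * en.n); en.v.resize(3 * en.n); en.f.resize(3 * en.n);
  for (int i = 0; i < en.nb; ++i)
    for (int d = 0; d < 3; ++d) {
      en.x[3 * i + d] = beadPos(i, d);
      en.v[3 * i + d] = beadVel(i, d);
    }
  for (int i = 0; i < en.nm; ++i)
    for (int d = 0; d < 3; ++d) {
      en.x[3 * (en.nb + i) + d] = binderPos(i, d);
      en.v[3 * (en.nb + i) + d] = binderVel(i, d);
    }
  double attCut = 0.0;
  for (int k = 0; k < epsMat.length(); ++k)
    if (epsMat[k] > 0.0) { attCut = rInt; break; }
  en.maxCut = std::max(std::sqrt(WCA_CUT2), attCut);
  en.skin = 0.3;

  bool extrActive = legs.nrow() > 0;
  ExtrusionSystem ex;
  if (extrActive)
    ex = makeExtrusion(legs, halted, en.nb, anchorOrient, anchorProb, kOff,
                       oneSided);

  Rng rng(static_cast<uint64_t>(seed));
  double c1 = (zeta > 0.0) ? std::exp(-zeta * dt) : 1.0;
  double c2 = (zeta > 0.0) ? std::sqrt((1.0 - c1 * c1) * temp) : 0.0;

  int nFrames = (sampleEvery > 0) ? nSteps / sampleEvery : 0;
  NumericVector frames(static_cast<R_xlen_t>(nFrames) * en.nb * 3);
  NumericVector bframes(storeBinders ?
      static_cast<R_xlen_t>(nFrames) * en.nm * 3 : 0);
  NumericVector times(nFrames), keSeries(nFrames), peSeries(nFrames);
  int frame = 0;

  en.buildList();
  double pe = 0.0;
  en.forces(extrActive ? &ex : 0, false, &pe);

  for (int step = 1; step <= nSteps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * en.n; ++i) en.v[i] += 0.5 * dt * en.f[i];
    // A: half drift
    for (int i = 0; i < 3 * en.n; ++i) {
      double d = 0.5 * dt * en.v[i];
      en.x[i] += d; en.w[i] += d;
    }
    // O
    if (zeta > 0.0)
      for (int i = 0; i < 3 * en.n; ++i)
        en.v[i] = c1 * en.v[i] + c2 * rng.gauss();
    // A: half drift
    for (int i = 0; i < 3 * en.n; ++i) {
      double d = 0.5 * dt * en.v[i];
      en.x[i] += d; en.w[i] += d;
    }
    // extrusion update between force evaluations
    if (extrActive && stepInterval > 0 && step % stepInterval == 0)
      ex.update(rng);
    if (en.needRebuild()) en.buildList();
    bool sample = (sampleEvery > 0) && (step % sampleEvery == 0);
    en.forces(extrActive ? &ex : 0, sample, &pe);
    // B: half kick
    for (int i = 0; i < 3 * en.n; ++i) en.v[i] += 0.5 * dt * en.f[i];

    if (sample) {
      for (int i = 0; i < en.nb; ++i)
        for (int d = 0; d < 3; ++d)
          frames[static_cast<R_xlen_t>(frame) * en.nb * 3 + i + en.nb * d] =
              en.x[3 * i + d];
      if (storeBinders)
        for (int i = 0; i < en.nm; ++i)
          for (int d = 0; d < 3; ++d)
            bframes[static_cast<R_xlen_t>(frame) * en.nm * 3 + i + en.nm * d] =
                en.x[3 * (en.nb + i) + d];
      times[frame] = step;
      keSeries[frame] = en.kinetic();
      peSeries[frame] = pe;
      ++frame;
    }
    for (int i = 0; i < 3 * en.n; ++i)
      if (!std::isfinite(en.x[i]))
        stop("non-finite coordinate at step %d (dt too large?)", step);
  }

  NumericMatrix outBeadPos(en.nb, 3), outBeadVel(en.nb, 3);
  for (int i = 0; i < en.nb; ++i)
    for (int d = 0; d < 3; ++d) {
      outBeadPos(i, d) = en.x[3 * i + d];
      outBeadVel(i, d) = en.v[3 * i + d];
    }
  NumericMatrix outBinderPos(en.nm, 3), outBinderVel(en.nm, 3);
  for (int i = 0; i < en.nm; ++i)
    for (int d = 0; d < 3; ++d) {
      outBinderPos(i, d) = en.x[3 * (en.nb + i) + d];
      outBinderVel(i, d) = en.v[3 * (en.nb + i) + d];
    }
  List extrOut = R_NilValue;
  if (extrActive) {
    IntegerMatrix outLegs(ex.nExtr, 2);
    LogicalMatrix outHalt(ex.nExtr, 2);
    for (int e = 0; e < ex.nExtr; ++e) {
      outLegs(e, 0) = ex.legL[e]; outLegs(e, 1) = ex.legR[e];
      outHalt(e, 0) = ex.haltL[e] != 0; outHalt(e, 1) = ex.haltR[e] != 0;
    }
    extrOut = List::create(_["legs"] = outLegs, _["halted"] = outHalt,
                           _["loop_lengths"] = wrap(ex.loopLenAtDetach));
  }
  if (nFrames > 0) frames.attr("dim") = IntegerVector::create(en.nb, 3, nFrames);
  if (storeBinders && nFrames > 0)
    bframes.attr("dim") = IntegerVector::create(en.nm, 3, nFrames);
  return List::create(
      _["frames"] = frames, _["binder_frames"] = bframes, _["times"] = times,
      _["ke"] = keSeries, _["pe"] = peSeries,
      _["bead_pos"] = outBeadPos, _["bead_vel"] = outBeadVel,
      _["binder_pos"] = outBinderPos, _["binder_vel"] = outBinderVel,
      _["max_bond"] = std::sqrt(en.maxBond2), _["extrusion"] = extrOut);
}

// Forces via neighbour list or plain all-pairs double loop; used to verify
// the cell/Verlet list against the brute-force reference.
// [[Rcpp::export(name = ".cpp_compute_forces")]]
NumericMatrix cpp_compute_forces(NumericMatrix beadPos, NumericMatrix binderPos,
                                 IntegerVector binderTypeIdx,
                                 NumericMatrix epsMat, double rInt,
                                 double boxL, bool allPairs,
                                 double R0, double kFene) {
  Engine en;
  en.nb = beadPos.nrow(); en.nm = binderPos.nrow(); en.n = en.nb + en.nm;
  en.boxL = boxL; en.rInt = rInt; en.R0 = R0; en.kFene = kFene;
  en.kSpring = 0.0; en.rEq = 0.0;
  en.nTypes = epsMat.nrow();
  en.maxBond2 = 0.0;
  en.epsPB.assign(epsMat.begin(), epsMat.end());
  en.binderType.assign(binderTypeIdx.begin(), binderTypeIdx.end());
  en.x.resize(3 * en.n); en.v.assign(3 * en.n, 0.0); en.f.resize(3 * en.n);
  for (int i = 0; i < en.nb; ++i)
    for (int d = 0; d < 3; ++d) en.x[3 * i + d] = beadPos(i, d);
  for (int i = 0; i < en.nm; ++i)
    for (int d = 0; d < 3; ++d) en.x[3 * (en.nb + i) + d] = binderPos(i, d);
  double attCut = 0.0;
  for (int k = 0; k < epsMat.length(); ++k)
    if (epsMat[k] > 0.0) { attCut = rInt; break; }
  en.maxCut = std::max(std::sqrt(WCA_CUT2), attCut);
  en.skin = 0.3;
  if (allPairs) {
    en.nbrI.clear(); en.nbrJ.clear(); en.nbrEps.clear();
    for (int i = 0; i < en.n; ++i)
      for (int j = i + 1; j < en.n; ++j) {
        en.nbrI.push_back(i); en.nbrJ.push_back(j);
        en.nbrEps.push_back(en.pairEps(i, j));
      }
    en.x0 = en.x;
    en.refreshWrapped();
  } else {
    en.buildList();
  }
  en.forces(0, false, 0);
  NumericMatrix out(en.n, 3);
  for (int i = 0; i < en.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = en.f[3 * i + d];
  return out;
}

// Self-avoiding walk initial conformation: unit steps, pairwise clearance 1.
// [[Rcpp::export(name = ".cpp_init_saw")]]
NumericMatrix cpp_init_saw(int nBeads, double boxL, int seed, int maxRestarts) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(nBeads, 3);
  double half = boxL / 2.0;
  for (int attempt = 0; attempt <= maxRestarts; ++attempt) {
    std::vector<double> px(nBeads), py(nBeads), pz(nBeads);
    px[0] = half; py[0] = half; pz[0] = half;
    bool ok = true;
    for (int i = 1; i < nBeads && ok; ++i) {
      bool placed = false;
      for (int t = 0; t < 80; ++t) {
        // uniform random unit vector
        double u = 2.0 * rng.runif() - 1.0, phi = 2.0 * M_PI * rng.runif();
        double s = std::sqrt(1.0 - u * u);
        double cx = px[i - 1] + s * std::cos(phi);
        double cy = py[i - 1] + s * std::sin(phi);
        double cz = pz[i - 1] + u;
        if (cx < 0.0 || cx >= boxL || cy < 0.0 || cy >= boxL ||
            cz < 0.0 || cz >= boxL)
          continue;
        bool clash = false;
        for (int j = 0; j < i - 1; ++j) {
          double dx = cx - px[j], dy = cy - py[j], dz = cz - pz[j];
          if (dx * dx + dy * dy + dz * dz < 1.0) { clash = true; break; }
        }
        if (!clash) {
          px[i] = cx; py[i] = cy; pz[i] = cz;
          placed = true;
          break;
        }
      }
      if (!placed) ok = false;
    }
    if (ok) {
      for (int i = 0; i < nBeads; ++i) {
        out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
      }
      return out;
    }
  }
  stop("self-avoiding walk could not be placed: box too small for %d beads",
       nBeads);
  return out;  // unreached
}
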