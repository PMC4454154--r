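// Core Monte Carlo kernels: incremental energy changes, Metropolis sweeps,
// the full drying run, and connected-component labeling of height maps.
//
// Cell codes (shared with the R side): 0 = substrate, 1 = liquid,
// 2 = vapor, 3 = particle. Layers are 0..H with layer 0 = substrate;
// lateral coordinates are periodic, the vertical direction is not, and
// cells outside [0, H] behave as vapor (zero couplings).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

static const int K_SUB = 0, K_LIQ = 1, K_VAP = 2, K_PAR = 3;

// 6 nearest (weight 1) followed by 12 next-nearest (weight 1/sqrt(2)).
static const int OFF[18][3] = {
    {1, 0, 0},  {-1, 0, 0}, {0, 1, 0},  {0, -1, 0},  {0, 0, 1},  {0, 0, -1},
    {1, 1, 0},  {1, -1, 0}, {-1, 1, 0}, {-1, -1, 0}, {1, 0, 1},  {1, 0, -1},
    {-1, 0, 1}, {-1, 0, -1}, {0, 1, 1}, {0, 1, -1},  {0, -1, 1}, {0, -1, -1}};

static inline double offWeight(int m) { return m < 6 ? 1.0 : M_SQRT1_2; }

struct Lattice {
  int D, H;               // base side, number of fluid layers
  std::vector<int> g;     // length D*D*(H+1), index x + D*(y + D*l)
  std::vector<int> p1, m1;  // lateral wrap tables: (i +/- 1) mod D
  void initWrap() {
    p1.resize(D);
    m1.resize(D);
    for (int i = 0; i < D; ++i) {
      p1[i] = (i + 1) % D;
      m1[i] = (i - 1 + D) % D;
    }
  }
  inline int idx(int x, int y, int l) const { return x + D * (y + D * l); }
  inline int wrap(int a) const {
    int r = a % D;
    return r < 0 ? r + D : r;
  }
  // kind seen from inside the grid; vertical exterior acts as vapor
  inline int kindAt(int x, int y, int l) const {
    if (l < 0 || l > H) return K_VAP;
    return g[idx(wrap(x), wrap(y), l)];
  }
};

struct Couplings {
  double eps[4][4];  // symmetric; vapor rows/cols and sub-sub are zero
  double scale;      // coordination-consistency factor c = 1/(1+sqrt(2))
};

static Couplings makeCouplings(const NumericMatrix& epsMat, double scale) {
  Couplings cp;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) cp.eps[a][b] = epsMat(a, b);
  cp.scale = scale;
  return cp;
}

// Weighted coupling sum of a hypothetical kind `k` sitting at (x,y,l),
// over the 18-cell stencil. Optionally exclude one neighbor site.
static double stencilSum(const Lattice& lat, const Couplings& cp, int k,
                         int x, int y, int l, int exX = -1, int exY = -1,
                         int exL = -1) {
  double s = 0.0;
  for (int m = 0; m < 18; ++m) {
    int nx = x + OFF[m][0], ny = y + OFF[m][1], nl = l + OFF[m][2];
    if (nl < 0 || nl > lat.H) continue;  // exterior: vapor, zero coupling
    int wx = lat.wrap(nx), wy = lat.wrap(ny);
    if (wx == exX && wy == exY && nl == exL) continue;
    s += offWeight(m) * cp.eps[k][lat.g[lat.idx(wx, wy, nl)]];
  }
  return s;
}

// Unrolled stencil sum (no exclusions) for the sweep hot path; uses the
// lateral wrap tables instead of per-neighbor modulo.
static double stencilSumFast(const Lattice& lat, const Couplings& cp, int k,
                             int x, int y, int l) {
  const double* e = cp.eps[k];
  const int D = lat.D;
  const int xp = lat.p1[x], xm = lat.m1[x];
  const int yp = lat.p1[y], ym = lat.m1[y];
  const int* g = lat.g.data();
  const int base = D * D * l;
  double sN = e[g[base + xp + D * y]] + e[g[base + xm + D * y]] +
              e[g[base + x + D * yp]] + e[g[base + x + D * ym]];
  double sD = e[g[base + xp + D * yp]] + e[g[base + xp + D * ym]] +
              e[g[base + xm + D * yp]] + e[g[base + xm + D * ym]];
  if (l + 1 <= lat.H) {
    const int b = base + D * D;
    sN += e[g[b + x + D * y]];
    sD += e[g[b + xp + D * y]] + e[g[b + xm + D * y]] +
          e[g[b + x + D * yp]] + e[g[b + x + D * ym]];
  }
  if (l - 1 >= 0) {
    const int b = base - D * D;
    sN += e[g[b + x + D * y]];
    sD += e[g[b + xp + D * y]] + e[g[b + xm + D * y]] +
          e[g[b + x + D * yp]] + e[g[b + x + D * ym]];
  }
  return sN + M_SQRT1_2 * sD;
}

// Energy change of toggling liquid <-> vapor at (x,y,l).
static double deltaFlipAt(const Lattice& lat, const Couplings& cp, double mu,
                          int x, int y, int l) {
  double bond = cp.scale * stencilSumFast(lat, cp, K_LIQ, x, y, l);
  int k = lat.g[lat.idx(x, y, l)];
  // evaporation (liquid -> vapor) loses the bonds and the -mu term
  return (k == K_LIQ) ? bond + mu : -(bond + mu);
}

// Energy change of swapping a particle at p with a nearest-neighbor liquid
// cell at q. The mu term and the p-q pair coupling cancel.
static double deltaSwapAt(const Lattice& lat, const Couplings& cp, int px,
                          int py, int pl, int qx, int qy, int ql) {
  double sp = stencilSum(lat, cp, K_PAR, px, py, pl, qx, qy, ql);
  double lp = stencilSum(lat, cp, K_LIQ, px, py, pl, qx, qy, ql);
  double sq = stencilSum(lat, cp, K_LIQ, qx, qy, ql, px, py, pl);
  double nq = stencilSum(lat, cp, K_PAR, qx, qy, ql, px, py, pl);
  return cp.scale * (sp + sq - lp - nq);
}

// Deterministic, implementation-independent draws from mt19937_64.
static inline double runif53(std::mt19937_64& rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
}
static inline std::size_t rIndex(std::mt19937_64& rng, std::size_t n) {
  return static_cast<std::size_t>(rng() % n);
}

static inline bool metropolis(double dE, double kT, std::mt19937_64& rng) {
  double u = runif53(rng);  // always consumed, one draw per evaluated move
  return u < std::exp(-dE / kT);
}

// One evaporation/condensation sweep: every fluid (liquid or vapor) cell is
// visited once in freshly shuffled order; accepted flips apply immediately.
static int sweepFluidCore(Lattice& lat, const Couplings& cp, double mu,
                          double kT, std::mt19937_64& rng, long& liquid) {
  std::vector<int> cells;
  cells.reserve(static_cast<std::size_t>(lat.D) * lat.D * lat.H);
  const int n = lat.D * lat.D * (lat.H + 1);
  for (int i = lat.D * lat.D; i < n; ++i)  // skip substrate layer
    if (lat.g[i] == K_LIQ || lat.g[i] == K_VAP) cells.push_back(i);
  // Fisher-Yates shuffle
  for (std::size_t i = cells.size(); i > 1; --i) {
    std::size_t j = rIndex(rng, i);
    std::swap(cells[i - 1], cells[j]);
  }
  int accepted = 0;
  const int DD = lat.D * lat.D;
  // single-entry Boltzmann cache: bulk liquid (early) and bulk vapor
  // (late) visits repeat the same dE almost every time
  double lastDE = std::numeric_limits<double>::quiet_NaN(), lastP = 0.0;
  for (std::size_t c = 0; c < cells.size(); ++c) {
    int i = cells[c];
    int l = i / DD, rem = i % DD, y = rem / lat.D, x = rem % lat.D;
    double dE = deltaFlipAt(lat, cp, mu, x, y, l);
    double u = runif53(rng);
    bool accept;
    if (dE <= 0.0) {
      accept = true;
    } else {
      if (dE != lastDE) {
        lastDE = dE;
        lastP = std::exp(-dE / kT);
      }
      accept = u < lastP;
    }
    if (accept) {
      if (lat.g[i] == K_LIQ) {
        lat.g[i] = K_VAP;
        --liquid;
      } else {
        lat.g[i] = K_LIQ;
        ++liquid;
      }
      ++accepted;
    }
  }
  return accepted;
}

// One particle random-walk phase: each particle makes nMov attempts; the
// direction is drawn before checking the target, so immobile particles
// consume draws identically.
static int sweepParticlesCore(Lattice& lat, const Couplings& cp, double kT,
                              int nMov, std::mt19937_64& rng,
                              std::vector<int>& particles) {
  int accepted = 0;
  const int DD = lat.D * lat.D;
  for (std::size_t pi = 0; pi < particles.size(); ++pi) {
    for (int a = 0; a < nMov; ++a) {
      int i = particles[pi];
      int l = i / DD, rem = i % DD, y = rem / lat.D, x = rem % lat.D;
      int dir = static_cast<int>(rIndex(rng, 6));
      int qx = lat.wrap(x + OFF[dir][0]), qy = lat.wrap(y + OFF[dir][1]);
      int ql = l + OFF[dir][2];
      if (ql < 1 || ql > lat.H) continue;           // substrate or exterior
      int qi = lat.idx(qx, qy, ql);
      if (lat.g[qi] != K_LIQ) continue;             // walk only into liquid
      double dE = deltaSwapAt(lat, cp, x, y, l, qx, qy, ql);
      if (metropolis(dE, kT, rng)) {
        lat.g[i] = K_LIQ;
        lat.g[qi] = K_PAR;
        particles[pi] = qi;
        ++accepted;
      }
    }
  }
  return accepted;
}

static Lattice latticeFromR(const IntegerVector& grid, int D, int H) {
  Lattice lat;
  lat.D = D;
  lat.H = H;
  lat.g.assign(grid.begin(), grid.end());
  lat.initWrap();
  return lat;
}

// [[Rcpp::export]]
double cpp_delta_flip(IntegerVector grid, int D, int H, int x, int y, int l,
                      NumericMatrix epsMat, double scale, double mu) {
  Lattice lat = latticeFromR(grid, D, H);
  Couplings cp = makeCouplings(epsMat, scale);
  return deltaFlipAt(lat, cp, mu, x, y, l);
}

// [[Rcpp::export]]
double cpp_delta_swap(IntegerVector grid, int D, int H, int px, int py,
                      int pl, int qx, int qy, int ql, NumericMatrix epsMat,
                      double scale) {
  Lattice lat = latticeFromR(grid, D, H);
  Couplings cp = makeCouplings(epsMat, scale);
  return deltaSwapAt(lat, cp, px, py, pl, qx, qy, ql);
}

// [[Rcpp::export]]
List cpp_sweep_fluid(IntegerVector grid, int D, int H, NumericMatrix epsMat,
                     double scale, double mu, double kT, double seed) {
  Lattice lat = latticeFromR(grid, D, H);
  Couplings cp = makeCouplings(epsMat, scale);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  long liquid = 0;
  for (std::size_t i = 0; i < lat.g.size(); ++i)
    if (lat.g[i] == K_LIQ) ++liquid;
  int acc = sweepFluidCore(lat, cp, mu, kT, rng, liquid);
  return List::create(_["grid"] = IntegerVector(lat.g.begin(), lat.g.end()),
                      _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_sweep_particles(IntegerVector grid, int D, int H,
                         NumericMatrix epsMat, double scale, double kT,
                         int nMov, double seed) {
  Lattice lat = latticeFromR(grid, D, H);
  Couplings cp = makeCouplings(epsMat, scale);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::vector<int> particles;
  for (std::size_t i = 0; i < lat.g.size(); ++i)
    if (lat.g[i] == K_PAR) particles.push_back(static_cast<int>(i));
  int acc = sweepParticlesCore(lat, cp, kT, nMov, rng, particles);
  return List::create(_["grid"] = IntegerVector(lat.g.begin(), lat.g.end()),
                      _["accepted"] = acc);
}

// Full drying run: per step, nu is measured, mu = schedule(nu), then the
// fluid sweep and the particle phase execute; terminates at zero liquid or
// maxSteps. schedKind: 0 constant, 1 sigmoidal.
// [[Rcpp::export]]
List cpp_run(IntegerVector grid, int D, int H, NumericMatrix epsMat,
             double scale, double kT, int nMov, int maxSteps, double seed,
             int schedKind, double mu0, double delta, double sigma,
             double nuC, int snapInterval) {
  Lattice lat = latticeFromR(grid, D, H);
  Couplings cp = makeCouplings(epsMat, scale);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));

  std::vector<int> particles;
  long liquid = 0;
  for (std::size_t i = 0; i < lat.g.size(); ++i) {
    if (lat.g[i] == K_PAR) particles.push_back(static_cast<int>(i));
    if (lat.g[i] == K_LIQ) ++liquid;
  }
  const double nFluid = static_cast<double>(D) * D * H;
  const int DD = D * D;

  std::vector<double> tMu, tNu, tLiq;
  std::vector<int> tStep, tFlips, tSwaps;
  List snaps;
  std::vector<int> snapSteps;
  int step = 0;
  while (step < maxSteps) {
    ++step;
    int dried = 0;
    for (int i = DD; i < 2 * DD; ++i)  // layer 1: cell touching substrate
      if (lat.g[i] != K_LIQ) ++dried;
    double nu = dried / static_cast<double>(DD);
    double mu = mu0;
    if (schedKind == 1) mu = mu0 - delta / (1.0 + std::exp(-(nu - nuC) / sigma));

    int af = sweepFluidCore(lat, cp, mu, kT, rng, liquid);
    int as = sweepParticlesCore(lat, cp, kT, nMov, rng, particles);

    tStep.push_back(step);
    tMu.push_back(mu);
    tNu.push_back(nu);
    tLiq.push_back(liquid / nFluid);
    tFlips.push_back(af);
    tSwaps.push_back(as);
    if (snapInterval > 0 && step % snapInterval == 0) {
      snaps.push_back(IntegerVector(lat.g.begin(), lat.g.end()));
      snapSteps.push_back(step);
    }
    if (liquid == 0) break;
    if (step % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["grid"] = IntegerVector(lat.g.begin(), lat.g.end()),
      _["step"] = IntegerVector(tStep.begin(), tStep.end()),
      _["mu"] = NumericVector(tMu.begin(), tMu.end()),
      _["nu"] = NumericVector(tNu.begin(), tNu.end()),
      _["liquidFraction"] = NumericVector(tLiq.begin(), tLiq.end()),
      _["acceptedFlips"] = IntegerVector(tFlips.begin(), tFlips.end()),
      _["acceptedSwaps"] = IntegerVector(tSwaps.begin(), tSwaps.end()),
      _["steps"] = step, _["snapshots"] = snaps,
      _["snapshotSteps"] = IntegerVector(snapSteps.begin(), snapSteps.end()));
}

// Connected components of {occ != 0} under 4- or 8-connectivity, with or
// without lateral periodic wrapping. Labels are 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix occ, int connectivity, bool periodic) {
  const int nr = occ.nrow(), nc = occ.ncol();
  IntegerMatrix lab(nr, nc);
  const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* dx = connectivity == 4 ? dx4 : dx8;
  const int* dy = connectivity == 4 ? dy4 : dy8;
  const int nd = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (occ(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.clear();
      stack.push_back(i + nr * j);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        for (int d = 0; d < nd; ++d) {
          int ni = ci + dx[d], nj = cj + dy[d];
          if (periodic) {
            ni = (ni % nr + nr) % nr;
            nj = (nj % nc + nc) % nc;
          } else if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) {
            continue;
          }
          if (occ(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nr * nj);
          }
        }
      }
    }
  }
  return lab;
}
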