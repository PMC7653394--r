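// Exact event-driven (Gillespie direct method) simulation of RCP models on a
// d-dimensional torus.  Per-agent pairwise rate sums are cached and updated
// locally after each event using cell lists (cells store packed copies of
// position and type so neighbourhood scans stream through memory);
// `naive = true` recomputes every pairwise sum from scratch after each event
// (the correctness oracle: with the same seed the event sequences must
// coincide).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct KernelC {
  int shape;            // 0 gaussian, 1 tophat
  double A, eps, trunc; // total integral, inverse length scale, truncation
  int d;
  // precomputed
  double trunc2, coef, eps2half, R2, flat;
  void prepare() {
    trunc2 = trunc * trunc;
    eps2half = eps * eps / 2.0;
    double c = (d == 2) ? (eps * eps / (2.0 * M_PI))
                        : (eps / std::sqrt(2.0 * M_PI));
    coef = A * c;
    double R = 1.0 / eps;
    R2 = R * R;
    flat = A * ((d == 2) ? 1.0 / (M_PI * R2) : 1.0 / (2.0 * R));
  }
  double evalR2(double r2) const {
    if (r2 > trunc2) return 0.0;
    if (shape == 0) {
      double e = eps2half * r2;
      if (e > 40.0) return 0.0;  // < 5e-18 of peak: numerically zero
      return coef * std::exp(-e);
    }
    return (r2 > R2) ? 0.0 : flat;
  }
  double truncated_integral() const {
    if (shape == 0) {
      if (d == 2) return A * (1.0 - std::exp(-eps2half * trunc2));
      return A * std::erf(eps * trunc / std::sqrt(2.0));
    }
    double f = std::min(1.0, trunc * eps);
    return A * ((d == 2) ? f * f : f);
  }
};

// reaction kinds
enum { K_CDEATH = 0, K_PDEATH = 1, K_BIRTH = 2, K_CATCONV = 3,
       K_CONSTCONV = 4 };

struct ReactionC {
  int kind;
  int rtype;                 // reactant / parent type (0-based)
  int product;               // product / offspring type, -1 if none
  double rate;               // constant rate (const kinds)
  KernelC kernel;            // valid for kernel-mediated kinds
  bool has_kernel;
  std::vector<int> catalysts;
  std::vector<char> isCat;   // indicator over types
};

struct CatRole {             // "agents of this type catalyze reaction rx"
  int rx;
  int rtype;                 // reactant type whose agents carry the sum
  int slot;                  // slot in that type's pairwise-sum vector
};

struct CellEntry {           // packed copy for streaming scans
  double x, y;
  int type, idx;
};

struct Fenwick {
  int n; std::vector<double> t;
  void init(int n_) { n = n_; t.assign(n + 1, 0.0); }
  void add(int i, double v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  double total() const {
    double s = 0; for (int i = n; i > 0; i -= i & -i) s += t[i]; return s;
  }
  // index of the bucket containing the prefix position `target`
  int search(double target) const {
    int pos = 0; int pw = 1; while ((pw << 1) <= n) pw <<= 1;
    for (; pw > 0; pw >>= 1)
      if (pos + pw <= n && t[pos + pw] < target) {
        pos += pw; target -= t[pos];
      }
    return std::min(pos, n - 1);
  }
};

struct Sim {
  // model
  int ntypes, d;
  double L, halfL;
  std::vector<ReactionC> rx;
  std::vector<double> constRate;              // per type
  std::vector<std::vector<int>> typeRx;       // reactions by reactant/parent
  std::vector<std::vector<int>> pwIdx;        // pairwise reactions by reactant
  std::vector<std::vector<CatRole>> catRoles; // by catalyst type
  std::vector<double> catRad;                 // per type: catalyst reach
  std::vector<double> ownRad;                 // per type: own pairwise reach
  int nSlotsPerAgent = 1;

  // agents (slot arrays)
  std::vector<double> x, y;
  std::vector<int> type, id;
  std::vector<char> alive;
  std::vector<double> psum;                   // flattened pairwise sums
  std::vector<int> cellOf, posInCell;
  std::vector<int> freeSlots;
  long long nAlive = 0;

  // cells
  int ncx, ncy;
  double csx;
  std::vector<std::vector<CellEntry>> cells;
  std::vector<double> cellRate;
  Fenwick fw;

  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};

  bool naive = false;
  long long nextId = 0;

  double minImage(double dv) const {
    if (dv > halfL) return dv - L;
    if (dv < -halfL) return dv + L;
    return dv;
  }
  int cellIndex(double px, double py) const {
    int ix = (int)(px / csx); if (ix >= ncx) ix = ncx - 1;
    int iy = (d == 2) ? (int)(py / csx) : 0; if (iy >= ncy) iy = ncy - 1;
    return ix + iy * ncx;
  }

  double* psumAt(int a) { return &psum[(size_t)a * nSlotsPerAgent]; }

  double agentRate(int a) {
    double r = constRate[type[a]];
    const double* p = psumAt(a);
    for (size_t s = 0; s < pwIdx[type[a]].size(); ++s) r += p[s];
    return r;
  }

  void addToCell(int a) {
    int c = cellIndex(x[a], y[a]);
    cellOf[a] = c; posInCell[a] = (int)cells[c].size();
    cells[c].push_back({x[a], y[a], type[a], a});
  }
  void removeFromCell(int a) {
    int c = cellOf[a]; int p = posInCell[a];
    CellEntry last = cells[c].back();
    cells[c][p] = last; posInCell[last.idx] = p;
    cells[c].pop_back();
  }
  void bumpCell(int c, double delta) {
    cellRate[c] += delta;
    fw.add(c, delta);
  }

  // One combined neighbourhood pass around agent a.  tOld >= 0: remove a's
  // catalyst contributions as that type; tNew >= 0: add contributions as
  // that type and rebuild a's own pairwise sums (type[a] must already be
  // tNew).  Fenwick updates are batched per cell.
  void scanUpdate(int a, int tOld, int tNew) {
    double rad = 0.0;
    bool ownNeeded = false;
    if (tOld >= 0) rad = std::max(rad, catRad[tOld]);
    if (tNew >= 0) {
      rad = std::max(rad, catRad[tNew]);
      rad = std::max(rad, ownRad[tNew]);
      double* p = psumAt(a);
      for (int s = 0; s < nSlotsPerAgent; ++s) p[s] = 0.0;
      ownNeeded = !pwIdx[tNew].empty();
    }
    bool oldRoles = tOld >= 0 && !catRoles[tOld].empty();
    bool newRoles = tNew >= 0 && !catRoles[tNew].empty();
    if (!oldRoles && !newRoles && !ownNeeded) return;
    if (rad <= 0.0) return;

    double rad2 = rad * rad;
    double x0 = x[a], y0 = y[a];
    double* own = psumAt(a);
    int kx = std::min(ncx / 2, (int)std::ceil(rad / csx));
    int ax = cellOf[a] % ncx, ay = cellOf[a] / ncx;
    int ky = (d == 2) ? kx : 0;
    int spanx = (2 * kx + 1 >= ncx) ? ncx : 2 * kx + 1;
    int spany = (d == 2) ? ((2 * ky + 1 >= ncy) ? ncy : 2 * ky + 1) : 1;
    for (int jy = 0; jy < spany; ++jy) {
      int iy = ((ay - ky + jy) % ncy + ncy) % ncy;
      for (int jx = 0; jx < spanx; ++jx) {
        int ic = ((ax - kx + jx) % ncx + ncx) % ncx + iy * ncx;
        std::vector<CellEntry>& cell = cells[ic];
        double cellDelta = 0.0;
        for (CellEntry& e : cell) {
          if (e.idx == a) continue;
          double dx = minImage(x0 - e.x);
          double r2 = dx * dx;
          if (d == 2) { double dy = minImage(y0 - e.y); r2 += dy * dy; }
          if (r2 > rad2) continue;
          int tb = e.type;
          double delta = 0.0;
          if (oldRoles)
            for (const CatRole& cr : catRoles[tOld]) {
              if (tb != cr.rtype) continue;
              double v = rx[cr.rx].kernel.evalR2(r2);
              if (v != 0.0) { psumAt(e.idx)[cr.slot] -= v; delta -= v; }
            }
          if (newRoles)
            for (const CatRole& cr : catRoles[tNew]) {
              if (tb != cr.rtype) continue;
              double v = rx[cr.rx].kernel.evalR2(r2);
              if (v != 0.0) { psumAt(e.idx)[cr.slot] += v; delta += v; }
            }
          if (ownNeeded)
            for (size_t s = 0; s < pwIdx[tNew].size(); ++s) {
              const ReactionC& R = rx[pwIdx[tNew][s]];
              if (R.isCat[tb]) {
                double v = R.kernel.evalR2(r2);
                if (v != 0.0) own[s] += v;
              }
            }
          cellDelta += delta;
        }
        if (cellDelta != 0.0) bumpCell(ic, cellDelta);
      }
      if (d == 1) break;
    }
  }

  int newSlot() {
    if (!freeSlots.empty()) {
      int s = freeSlots.back(); freeSlots.pop_back(); return s;
    }
    x.push_back(0); y.push_back(0); type.push_back(0); id.push_back(0);
    alive.push_back(0); cellOf.push_back(0); posInCell.push_back(0);
    psum.resize(psum.size() + nSlotsPerAgent, 0.0);
    return (int)x.size() - 1;
  }

  void insertAgent(long long agentId, int t, double px, double py) {
    int a = newSlot();
    x[a] = px; y[a] = py; type[a] = t; id[a] = (int)agentId; alive[a] = 1;
    addToCell(a);
    scanUpdate(a, -1, t);
    bumpCell(cellOf[a], agentRate(a));
    ++nAlive;
  }

  void removeAgent(int a) {
    bumpCell(cellOf[a], -agentRate(a));
    scanUpdate(a, type[a], -1);
    alive[a] = 0;
    removeFromCell(a);
    freeSlots.push_back(a);
    --nAlive;
  }

  void convertAgent(int a, int newType) {
    bumpCell(cellOf[a], -agentRate(a));
    int told = type[a];
    type[a] = newType;
    cells[cellOf[a]][posInCell[a]].type = newType;
    scanUpdate(a, told, newType);
    bumpCell(cellOf[a], +agentRate(a));
  }

  void rebuildRates() {
    for (size_t c = 0; c < cellRate.size(); ++c) cellRate[c] = 0.0;
    for (size_t a = 0; a < x.size(); ++a)
      if (alive[a]) cellRate[cellOf[a]] += agentRate((int)a);
    fw.init((int)cellRate.size());
    for (size_t c = 0; c < cellRate.size(); ++c)
      if (cellRate[c] != 0.0) fw.add((int)c, cellRate[c]);
  }

  // O(n^2) recomputation of all pairwise sums (the oracle path)
  void naiveRecomputeAll() {
    for (size_t a = 0; a < x.size(); ++a) {
      if (!alive[a]) continue;
      int t = type[(int)a];
      double* p = psumAt((int)a);
      for (int s = 0; s < nSlotsPerAgent; ++s) p[s] = 0.0;
      if (pwIdx[t].empty()) continue;
      for (size_t b = 0; b < x.size(); ++b) {
        if (b == a || !alive[b]) continue;
        double dx = minImage(x[a] - x[b]);
        double r2 = dx * dx;
        if (d == 2) { double dy = minImage(y[a] - y[b]); r2 += dy * dy; }
        for (size_t s = 0; s < pwIdx[t].size(); ++s) {
          const ReactionC& R = rx[pwIdx[t][s]];
          if (R.isCat[type[b]]) p[s] += R.kernel.evalR2(r2);
        }
      }
    }
    rebuildRates();
  }

  // displacement sampling (rejection inside truncation ball)
  void sampleDisp(const KernelC& k, double& dx, double& dy) {
    for (int it = 0; it < 100000; ++it) {
      if (k.shape == 0) {
        dx = norm(rng) / k.eps;
        dy = (d == 2) ? norm(rng) / k.eps : 0.0;
      } else {
        double R = 1.0 / k.eps;
        if (d == 2) {
          double r = R * std::sqrt(unif(rng)), th = 2.0 * M_PI * unif(rng);
          dx = r * std::cos(th); dy = r * std::sin(th);
        } else { dx = R * (2.0 * unif(rng) - 1.0); dy = 0.0; }
      }
      if (dx * dx + dy * dy <= k.trunc2) return;
    }
    stop("displacement sampling failed (kernel mass inside truncation ~ 0)");
  }

  double wrap(double v) const {
    v -= L * std::floor(v / L);
    if (v >= L) v -= L;
    if (v < 0.0) v = 0.0;
    return v;
  }
};

} // namespace

// [[Rcpp::export]]
List sim_rcp_cpp(int ntypes, List reactions, double L, int d,
                 NumericVector init_x, NumericVector init_y,
                 IntegerVector init_type, IntegerVector init_id,
                 NumericVector snapshot_times, double seed,
                 bool naive = false, double max_agents = 8e6) {
  Sim S;
  S.ntypes = ntypes; S.d = d; S.L = L; S.halfL = L / 2.0; S.naive = naive;
  S.rng.seed((uint64_t)seed);

  // ---- decode reactions
  double maxTrunc = 0.0;
  for (int j = 0; j < reactions.size(); ++j) {
    List r = reactions[j];
    ReactionC R;
    R.kind = as<int>(r["kind"]);
    R.rtype = as<int>(r["rtype"]);
    R.product = as<int>(r["product"]);
    R.rate = as<double>(r["rate"]);
    R.has_kernel = as<bool>(r["has_kernel"]);
    if (R.has_kernel) {
      R.kernel.shape = as<int>(r["kshape"]);
      R.kernel.A = as<double>(r["kA"]);
      R.kernel.eps = as<double>(r["keps"]);
      R.kernel.trunc = as<double>(r["ktrunc"]);
      R.kernel.d = d;
      R.kernel.prepare();
      maxTrunc = std::max(maxTrunc, R.kernel.trunc);
    }
    IntegerVector cats = r["catalysts"];
    R.catalysts.assign(cats.begin(), cats.end());
    R.isCat.assign(ntypes, 0);
    for (int c : R.catalysts) R.isCat[c] = 1;
    S.rx.push_back(R);
  }

  // ---- per-type tables
  S.constRate.assign(ntypes, 0.0);
  S.typeRx.assign(ntypes, {});
  S.pwIdx.assign(ntypes, {});
  S.catRoles.assign(ntypes, {});
  S.catRad.assign(ntypes, 0.0);
  S.ownRad.assign(ntypes, 0.0);
  for (size_t j = 0; j < S.rx.size(); ++j) {
    ReactionC& R = S.rx[j];
    S.typeRx[R.rtype].push_back((int)j);
    if (R.kind == K_CDEATH || R.kind == K_CONSTCONV)
      S.constRate[R.rtype] += R.rate;
    else if (R.kind == K_BIRTH)
      S.constRate[R.rtype] += R.kernel.truncated_integral();
    else {
      int slot = (int)S.pwIdx[R.rtype].size();
      S.pwIdx[R.rtype].push_back((int)j);
      S.ownRad[R.rtype] = std::max(S.ownRad[R.rtype], R.kernel.trunc);
      for (int c : R.catalysts) {
        S.catRoles[c].push_back({(int)j, R.rtype, slot});
        S.catRad[c] = std::max(S.catRad[c], R.kernel.trunc);
      }
    }
  }
  int maxSlots = 1;
  for (int t = 0; t < ntypes; ++t)
    maxSlots = std::max(maxSlots, (int)S.pwIdx[t].size());
  S.nSlotsPerAgent = maxSlots;

  // ---- cells (fine cells shrink the scanned area around each event)
  double target = maxTrunc > 0 ? maxTrunc / 3.0 : L;
  target = std::min(target, L);
  S.ncx = std::max(1, (int)std::floor(L / std::max(target, 1e-9)));
  S.ncx = std::min(S.ncx, 4096);
  S.csx = L / S.ncx;
  S.ncy = (d == 2) ? S.ncx : 1;
  S.cells.assign((size_t)S.ncx * S.ncy, {});
  S.cellRate.assign((size_t)S.ncx * S.ncy, 0.0);
  S.fw.init(S.ncx * S.ncy);

  // ---- initial configuration
  long long maxInitId = -1;
  for (int i = 0; i < init_x.size(); ++i) {
    int a = S.newSlot();
    S.x[a] = S.wrap(init_x[i]);
    S.y[a] = (d == 2) ? S.wrap(init_y[i]) : 0.0;
    S.type[a] = init_type[i] - 1;
    S.id[a] = init_id[i];
    S.alive[a] = 1;
    S.addToCell(a);
    maxInitId = std::max(maxInitId, (long long)init_id[i]);
    ++S.nAlive;
  }
  S.nextId = maxInitId + 1;
  S.naiveRecomputeAll();  // exact initial sums for both engines

  // ---- snapshot recording
  std::vector<double> out_t; std::vector<int> out_id, out_type;
  std::vector<double> out_x, out_y;
  int nextSnap = 0;
  auto record = [&](double st) {
    for (size_t a = 0; a < S.x.size(); ++a) {
      if (!S.alive[a]) continue;
      out_t.push_back(st); out_id.push_back(S.id[a]);
      out_type.push_back(S.type[a] + 1);
      out_x.push_back(S.x[a]); out_y.push_back(S.y[a]);
    }
  };

  double T = snapshot_times[snapshot_times.size() - 1];
  double t = 0.0;
  long long nEvents = 0;
  const long long rebuildEvery = 2000000;

  while (true) {
    double total = S.fw.total();
    double tNext;
    if (total <= 0.0 || S.nAlive == 0) tNext = R_PosInf;
    else tNext = t - std::log(1.0 - S.unif(S.rng)) / total;

    while (nextSnap < snapshot_times.size() &&
           snapshot_times[nextSnap] <= tNext) {
      record(snapshot_times[nextSnap]);
      ++nextSnap;
    }
    if (nextSnap >= snapshot_times.size() || tNext > T || !R_finite(tNext))
      break;
    t = tNext;

    // ---- select cell, agent, reaction
    double u = S.unif(S.rng) * total;
    int cell = S.fw.search(u);
    double acc = 0.0; int agent = -1;
    double target2 = S.unif(S.rng) * std::max(S.cellRate[cell], 0.0);
    const std::vector<CellEntry>& ca = S.cells[cell];
    for (const CellEntry& e : ca) {
      acc += S.agentRate(e.idx);
      if (acc > target2) { agent = e.idx; break; }
    }
    if (agent < 0) { if (ca.empty()) continue; agent = ca.back().idx; }

    int ty = S.type[agent];
    double u3 = S.unif(S.rng) * S.agentRate(agent);
    int chosen = -1;
    double acc2 = 0.0;
    for (int j : S.typeRx[ty]) {
      const ReactionC& R = S.rx[j];
      double comp;
      if (R.kind == K_CDEATH || R.kind == K_CONSTCONV) comp = R.rate;
      else if (R.kind == K_BIRTH) comp = R.kernel.truncated_integral();
      else {
        int slot = (int)(std::find(S.pwIdx[ty].begin(), S.pwIdx[ty].end(),
                                   j) - S.pwIdx[ty].begin());
        comp = S.psumAt(agent)[slot];
      }
      acc2 += comp;
      if (acc2 > u3) { chosen = j; break; }
    }
    if (chosen < 0 && !S.typeRx[ty].empty()) chosen = S.typeRx[ty].back();
    if (chosen < 0) continue;

    // ---- execute
    const ReactionC& R = S.rx[chosen];
    switch (R.kind) {
      case K_CDEATH: case K_PDEATH:
        S.removeAgent(agent);
        break;
      case K_BIRTH: {
        double dx, dy;
        S.sampleDisp(R.kernel, dx, dy);
        double px = S.wrap(S.x[agent] + dx);
        double py = (d == 2) ? S.wrap(S.y[agent] + dy) : 0.0;
        S.insertAgent(S.nextId++, R.product, px, py);
        break;
      }
      case K_CATCONV: case K_CONSTCONV:
        S.convertAgent(agent, R.product);
        break;
    }

    ++nEvents;
    if ((double)S.nAlive > max_agents)
      stop("population exceeded max_agents (%g): blow-up?", max_agents);
    if (naive) S.naiveRecomputeAll();
    else if (nEvents % rebuildEvery == 0) S.rebuildRates();
  }

  return List::create(
    _["time"] = out_t, _["id"] = out_id, _["type"] = out_type,
    _["x"] = out_x, _["y"] = out_y,
    _["n_events"] = (double)nEvents);
}
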