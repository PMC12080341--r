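// Core stochastic engine: Gillespie bridge kinetics inside fixed-duration
// reaction windows, alternating with uniform resampling of the disk centre
// from the feasible region (intersection of radius-R circles centred on the
// bridged ligand anchors).
//
// All geometry is exact: the adaptive candidate scheme below only ever
// excludes a circle when its disk provably contains the whole feasible
// region, so the vertex set, the constraining-bridge count and the sampling
// domain are those of the full intersection.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ with splitmix64 seeding; one independently seeded stream per
// replicate, derived from (base seed, replicate index).

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

static inline uint64_t streamSeed(double baseSeed, int replicate) {
  uint64_t x = (uint64_t)(int64_t)baseSeed;
  uint64_t s = 0;
  for (int i = 0; i < replicate; ++i) s = splitmix64(x);
  return s;
}

// --------------------------------------------------------- ligand grid ---

struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<int> start;  // CSR offsets, size nx*ny+1
  std::vector<int> items;  // ligand ids ordered by cell

  void build(const double *lx, const double *ly, int n, const double *ext,
             double cellSize) {
    x0 = ext[0];
    y0 = ext[2];
    cell = cellSize;
    nx = std::max(1, (int)std::ceil((ext[1] - ext[0]) / cell));
    ny = std::max(1, (int)std::ceil((ext[3] - ext[2]) / cell));
    std::vector<int> count((size_t)nx * ny + 1, 0);
    std::vector<int> code(n);
    for (int i = 0; i < n; ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)((lx[i] - x0) / cell)));
      int iy = std::min(ny - 1, std::max(0, (int)((ly[i] - y0) / cell)));
      code[i] = ix + nx * iy;
      ++count[code[i] + 1];
    }
    for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
    start = count;
    items.assign(n, 0);
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) items[cursor[code[i]]++] = i;
  }

  // visit candidate ligands in cells overlapping the disk
  template <class F>
  void forDisk(const double *lx, const double *ly, double cx, double cy,
               double R, F f) const {
    int ix0 = std::max(0, (int)((cx - R - x0) / cell));
    int ix1 = std::min(nx - 1, (int)((cx + R - x0) / cell));
    int iy0 = std::max(0, (int)((cy - R - y0) / cell));
    int iy1 = std::min(ny - 1, (int)((cy + R - y0) / cell));
    const double R2 = R * R;
    for (int iy = iy0; iy <= iy1; ++iy) {
      double cy0 = y0 + iy * cell, cy1 = cy0 + cell;
      double dy = (cy < cy0) ? (cy0 - cy) : (cy > cy1 ? cy - cy1 : 0.0);
      for (int ix = ix0; ix <= ix1; ++ix) {
        double cx0 = x0 + ix * cell, cx1 = cx0 + cell;
        double dx = (cx < cx0) ? (cx0 - cx) : (cx > cx1 ? cx - cx1 : 0.0);
        if (dx * dx + dy * dy > R2) continue;  // cell fully outside disk
        int c = ix + nx * iy;
        for (int k = start[c]; k < start[c + 1]; ++k) f(items[k]);
      }
    }
  }
};

// ----------------------------------------------------- region geometry ---

struct RegionResult {
  std::vector<double> vx, vy;  // boundary vertices
  std::vector<int> va, vb;     // owning anchors per vertex (indices into ord)
  std::vector<int> cons;       // constraining anchor indices (0-based, caller's)
  double rReg;                 // max distance region <-> current centre
  int nCand;                   // candidates used (prefix of ord)
};

// anchors: coordinate arrays and an index vector 'ord' sorted by distance to
// (cx, cy) descending, with distances 'd' aligned to ord. 'ord' may be a
// truncated prefix of the full anchor set, in which case 'dNext' is the
// largest distance among the excluded anchors (-1 if none): the function
// returns false when the exact region might involve one of those, so the
// caller must retry with a longer prefix. A circle is excluded only when its
// disk provably contains disk(centre, rReg), hence the whole region.
static bool computeRegion(const double *ax, const double *ay,
                          const std::vector<int> &ord,
                          const std::vector<double> &d, double dNext,
                          double R, double cx, double cy, RegionResult &out) {
  const int nb = (int)ord.size();
  out.vx.clear(); out.vy.clear(); out.va.clear(); out.vb.clear();
  out.cons.clear();
  const double tol = 1e-9 * R + 1e-12;
  if (nb == 1 && dNext < 0) {
    out.cons.push_back(ord[0]);
    out.rReg = R + d[0];
    out.nCand = 1;
    return true;
  }
  if (nb == 1) return false;  // truncated to one anchor: cannot certify
  int k = std::min(nb, 8);
  while (true) {
    out.vx.clear(); out.vy.clear(); out.va.clear(); out.vb.clear();
    double rReg = 0.0;
    for (int i = 0; i < k; ++i) {
      const double xi = ax[ord[i]], yi = ay[ord[i]];
      for (int j = i + 1; j < k; ++j) {
        const double xj = ax[ord[j]], yj = ay[ord[j]];
        const double dx = xj - xi, dy = yj - yi;
        const double dd2 = dx * dx + dy * dy;
        if (dd2 <= 0 || dd2 >= 4.0 * R * R) continue;
        const double dd = std::sqrt(dd2);
        const double h = std::sqrt(R * R - 0.25 * dd2);
        const double mx = 0.5 * (xi + xj), my = 0.5 * (yi + yj);
        const double ux = -dy / dd, uy = dx / dd;  // unit perpendicular
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          const double px = mx + sgn * h * ux, py = my + sgn * h * uy;
          bool inside = true;
          for (int m = 0; m < k && inside; ++m) {
            if (m == i || m == j) continue;
            const double ex = px - ax[ord[m]], ey = py - ay[ord[m]];
            if (ex * ex + ey * ey > (R + tol) * (R + tol)) inside = false;
          }
          if (inside) {
            out.vx.push_back(px);
            out.vy.push_back(py);
            out.va.push_back(i);
            out.vb.push_back(j);
            const double rx = px - cx, ry = py - cy;
            const double rr = std::sqrt(rx * rx + ry * ry);
            if (rr > rReg) rReg = rr;
          }
        }
      }
    }
    if (out.vx.empty())
      stop("feasible region has no boundary vertices: degenerate bridge geometry");
    out.rReg = rReg;
    if (k < nb && d[k] >= R - rReg - tol) {
      k = std::min(nb, 2 * k);
      continue;
    }
    if (k == nb && dNext >= 0 && dNext >= R - rReg - tol)
      return false;  // prefix too short: an excluded circle may matter
    break;
  }
  out.nCand = k;
  // constraining anchors = those owning at least one boundary vertex
  std::vector<char> seen(k, 0);
  for (size_t v = 0; v < out.va.size(); ++v) {
    seen[out.va[v]] = 1;
    seen[out.vb[v]] = 1;
  }
  for (int i = 0; i < k; ++i)
    if (seen[i]) out.cons.push_back(ord[i]);
  return true;
}

// uniform sample from the feasible region described by 'reg'
static void sampleRegion(const double *ax, const double *ay,
                         const std::vector<int> &ord, double R, double cx,
                         double cy, const RegionResult &reg, Xoshiro &rng,
                         double &nx_, double &ny_) {
  if (ord.size() == 1) {  // closed form: uniform in a disk
    const double r = R * std::sqrt(rng.unif());
    const double th = 6.283185307179586476925286766559 * rng.unif();
    nx_ = ax[ord[0]] + r * std::cos(th);
    ny_ = ay[ord[0]] + r * std::sin(th);
    return;
  }
  const double rr = reg.rReg;
  const double R2 = R * R;
  const int k = reg.nCand;
  for (long it = 0; it < 1000000L; ++it) {
    const double px = cx + (2.0 * rng.unif() - 1.0) * rr;
    const double py = cy + (2.0 * rng.unif() - 1.0) * rr;
    bool ok = true;
    for (int m = 0; m < k && ok; ++m) {
      const double ex = px - ax[ord[m]], ey = py - ay[ord[m]];
      if (ex * ex + ey * ey > R2) ok = false;
    }
    if (ok) {
      nx_ = px;
      ny_ = py;
      return;
    }
  }
  stop("feasible-region sampler exceeded 1e6 proposals (rReg = %g, k = %d, "
       "nb = %d): geometry bug", reg.rReg, reg.nCand, (int)ord.size());
}

// ------------------------------------------------------ Gillespie window -

struct WindowCounts {
  int nBind = 0, nUnbind = 0;
};

// One reaction window of duration dt with the disk frozen. 'cand' holds the
// eligible ligands (free at window start and under the disk); 'stampOf' marks
// window membership so a candidate that binds and unbinds again becomes
// eligible once more, while a bridge present at window start that breaks does
// not (its ligand was not free at window start). The event whose cumulative
// time would exceed dt is discarded.
// The parallel arrays candD2 / bridgeD2 carry squared distances of each
// candidate / bridge anchor to the (frozen) disk centre, so the move step
// that follows needs no extra scan; they are kept aligned through the
// swap-pop updates below.
static WindowCounts gillespieWindow(
    std::vector<int> &cand, std::vector<double> &candD2,
    std::vector<int> &candIdxOf, std::vector<int> &stampOf, int stamp,
    std::vector<int> &bridges, std::vector<double> &bridgeD2,
    std::vector<int> &bridgeIdxOf, std::vector<char> &bound, int &freeR,
    double kOnPair, double kOff, double dt, Xoshiro &rng) {
  WindowCounts ev;
  double tcum = 0.0;
  while (true) {
    const double aOn =
        (freeR > 0 && !cand.empty()) ? kOnPair * freeR * (double)cand.size()
                                     : 0.0;
    const double aOff = kOff * (double)bridges.size();
    const double aTot = aOn + aOff;
    if (aTot <= 0.0) break;
    tcum += -std::log(rng.unif()) / aTot;
    if (tcum > dt) break;  // final event truncated, not applied
    if (rng.unif() * aTot < aOn) {
      int j = (int)(rng.unif() * (double)cand.size());
      if (j >= (int)cand.size()) j = (int)cand.size() - 1;
      const int lig = cand[j];
      const double d2 = candD2[j];
      cand[j] = cand.back();
      candD2[j] = candD2.back();
      candIdxOf[cand[j]] = j;
      cand.pop_back();
      candD2.pop_back();
      bound[lig] = 1;
      bridgeIdxOf[lig] = (int)bridges.size();
      bridges.push_back(lig);
      bridgeD2.push_back(d2);
      --freeR;
      ++ev.nBind;
    } else {
      int b = (int)(rng.unif() * (double)bridges.size());
      if (b >= (int)bridges.size()) b = (int)bridges.size() - 1;
      const int lig = bridges[b];
      const double d2 = bridgeD2[b];
      bridges[b] = bridges.back();
      bridgeD2[b] = bridgeD2.back();
      bridgeIdxOf[bridges[b]] = b;
      bridges.pop_back();
      bridgeD2.pop_back();
      bridgeIdxOf[lig] = -1;
      bound[lig] = 0;
      ++freeR;
      ++ev.nUnbind;
      if (stampOf[lig] == stamp) {  // was eligible at window start
        candIdxOf[lig] = (int)cand.size();
        cand.push_back(lig);
        candD2.push_back(d2);
      }
    }
  }
  return ev;
}

// ------------------------------------------------------------- exports ---

// [[Rcpp::export(name = ".feasibleRegionCpp")]]
List feasibleRegionCpp(NumericMatrix anchors, double R,
                       NumericVector center) {
  const int nb = anchors.nrow();
  if (nb < 1) stop("feasible region requires at least one bridge");
  std::vector<double> ax(nb), ay(nb), d(nb);
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) {
    ax[i] = anchors(i, 0);
    ay[i] = anchors(i, 1);
    ord[i] = i;
  }
  std::vector<double> dist(nb);
  for (int i = 0; i < nb; ++i) {
    const double dx = ax[i] - center[0], dy = ay[i] - center[1];
    dist[i] = std::sqrt(dx * dx + dy * dy);
    if (dist[i] > R * (1.0 + 1e-9))
      stop("anchor %d lies outside the disk: centre is not in the region",
           i + 1);
  }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return dist[a] > dist[b]; });
  for (int i = 0; i < nb; ++i) d[i] = dist[ord[i]];
  RegionResult reg;
  computeRegion(ax.data(), ay.data(), ord, d, -1.0, R, center[0], center[1], reg);
  NumericMatrix verts((int)reg.vx.size(), 2);
  for (size_t v = 0; v < reg.vx.size(); ++v) {
    verts(v, 0) = reg.vx[v];
    verts(v, 1) = reg.vy[v];
  }
  IntegerVector cons((int)reg.cons.size());
  for (size_t i = 0; i < reg.cons.size(); ++i) cons[i] = reg.cons[i] + 1;
  std::sort(cons.begin(), cons.end());
  return List::create(_["vertices"] = verts, _["constraining"] = cons,
                      _["rReg"] = reg.rReg);
}

// [[Rcpp::export(name = ".moveStepCpp")]]
List moveStepCpp(NumericMatrix anchors, double R, NumericVector center,
                 double seed) {
  const int nb = anchors.nrow();
  if (nb < 1) stop("move step requires at least one bridge");
  std::vector<double> ax(nb), ay(nb), d(nb), dist(nb);
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) {
    ax[i] = anchors(i, 0);
    ay[i] = anchors(i, 1);
    ord[i] = i;
    const double dx = ax[i] - center[0], dy = ay[i] - center[1];
    dist[i] = std::sqrt(dx * dx + dy * dy);
  }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return dist[a] > dist[b]; });
  for (int i = 0; i < nb; ++i) d[i] = dist[ord[i]];
  RegionResult reg;
  computeRegion(ax.data(), ay.data(), ord, d, -1.0, R, center[0], center[1], reg);
  uint64_t x = (uint64_t)(int64_t)seed;
  Xoshiro rng(splitmix64(x));
  double nx_, ny_;
  sampleRegion(ax.data(), ay.data(), ord, R, center[0], center[1], reg, rng,
               nx_, ny_);
  return List::create(_["center"] = NumericVector::create(nx_, ny_),
                      _["nCb"] = (int)reg.cons.size());
}

// [[Rcpp::export(name = ".reactionWindowCpp")]]
List reactionWindowCpp(NumericVector ligX, NumericVector ligY,
                       IntegerVector bridgesIn, int nReceptors,
                       NumericVector center, double R, double kOnPair,
                       double kOff, double dt, double seed) {
  const int NL = ligX.size();
  std::vector<char> bound(NL, 0);
  std::vector<int> bridges, bridgeIdxOf(NL, -1);
  for (int i = 0; i < bridgesIn.size(); ++i) {
    const int lig = bridgesIn[i] - 1;
    if (lig < 0 || lig >= NL) stop("bridge ligand id out of range");
    if (bound[lig]) stop("duplicate bridge on ligand %d", lig + 1);
    bound[lig] = 1;
    bridgeIdxOf[lig] = (int)bridges.size();
    bridges.push_back(lig);
  }
  int freeR = nReceptors - (int)bridges.size();
  if (freeR < 0) stop("more bridges than receptors");
  std::vector<int> cand, candIdxOf(NL, -1), stampOf(NL, 0);
  std::vector<double> candD2, bridgeD2;
  for (size_t b = 0; b < bridges.size(); ++b) {
    const double dx = ligX[bridges[b]] - center[0],
                 dy = ligY[bridges[b]] - center[1];
    bridgeD2.push_back(dx * dx + dy * dy);
  }
  const double R2 = R * R;
  for (int i = 0; i < NL; ++i) {
    if (bound[i]) continue;
    const double dx = ligX[i] - center[0], dy = ligY[i] - center[1];
    const double dd2 = dx * dx + dy * dy;
    if (dd2 <= R2) {
      stampOf[i] = 1;
      candIdxOf[i] = (int)cand.size();
      cand.push_back(i);
      candD2.push_back(dd2);
    }
  }
  uint64_t x = (uint64_t)(int64_t)seed;
  Xoshiro rng(splitmix64(x));
  WindowCounts ev;
  if (dt > 0)
    ev = gillespieWindow(cand, candD2, candIdxOf, stampOf, 1, bridges,
                         bridgeD2, bridgeIdxOf, bound, freeR, kOnPair, kOff,
                         dt, rng);
  IntegerVector out((int)bridges.size());
  for (size_t i = 0; i < bridges.size(); ++i) out[i] = bridges[i] + 1;
  std::sort(out.begin(), out.end());
  return List::create(_["bridges"] = out, _["nBind"] = ev.nBind,
                      _["nUnbind"] = ev.nUnbind);
}

// [[Rcpp::export(name = ".runTrajectoryCpp")]]
List runTrajectoryCpp(NumericVector ligX, NumericVector ligY,
                      NumericVector extent, double R, double kOnPair,
                      double kOff, double dt, double tTotal, int nReceptors,
                      double baseSeed, int replicate, bool terminateOnDetach,
                      NumericVector center0, int recordEvery,
                      IntegerVector bridgesIn) {
  const int NL = ligX.size();
  double ext[4] = {extent[0], extent[1], extent[2], extent[3]};
  Grid grid;
  grid.build(&ligX[0], &ligY[0], NL, ext, std::max(R / 4.0, 1e-6));

  std::vector<char> bound(NL, 0);
  std::vector<int> bridges, bridgeIdxOf(NL, -1);
  for (int i = 0; i < bridgesIn.size(); ++i) {
    const int lig = bridgesIn[i] - 1;
    bound[lig] = 1;
    bridgeIdxOf[lig] = (int)bridges.size();
    bridges.push_back(lig);
  }
  int freeR = nReceptors - (int)bridges.size();
  if (freeR < 0) stop("more initial bridges than receptors");

  std::vector<int> cand, candIdxOf(NL, -1), stampOf(NL, 0);
  std::vector<double> candD2, bridgeD2(bridges.size(), 0.0);
  std::vector<int> selIdx, ordLig;
  std::vector<double> dOrd;

  Xoshiro rng(streamSeed(baseSeed, replicate));
  double cx = center0[0], cy = center0[1];
  double t = 0.0;
  const long nWindows = (long)std::ceil(tTotal / dt - 1e-12);
  std::string status = "ok";

  std::vector<double> rows;  // t, x, y, n_b, n_cb, n_bind, n_unbind
  rows.reserve(8 * (size_t)(nWindows / recordEvery + 2));
  int accBind = 0, accUnbind = 0, lastNcb = 0;
  auto record = [&]() {
    rows.push_back(t);
    rows.push_back(cx);
    rows.push_back(cy);
    rows.push_back((double)bridges.size());
    rows.push_back((double)lastNcb);
    rows.push_back((double)accBind);
    rows.push_back((double)accUnbind);
    accBind = accUnbind = 0;
  };
  record();  // initial sample at t = 0

  int stamp = 0;
  RegionResult reg;
  for (long w = 1; w <= nWindows; ++w) {
    // one grid pass over the disk refreshes everything the window needs:
    // free ligands under the disk become eligible candidates, and bound
    // ones (all bridges lie under the disk by invariant) get their anchor
    // distance to the frozen centre written into bridgeD2, which the move
    // step consumes without a second scan
    ++stamp;
    cand.clear();
    candD2.clear();
    const double R2 = R * R;
    int seenBound = 0;
    grid.forDisk(&ligX[0], &ligY[0], cx, cy, R, [&](int i) {
      const double dx = ligX[i] - cx, dy = ligY[i] - cy;
      const double dd2 = dx * dx + dy * dy;
      if (bound[i]) {
        bridgeD2[bridgeIdxOf[i]] = dd2;
        ++seenBound;
      } else if (dd2 <= R2) {
        stampOf[i] = stamp;
        candIdxOf[i] = (int)cand.size();
        cand.push_back(i);
        candD2.push_back(dd2);
      }
    });
    if (seenBound != (int)bridges.size())
      stop("bridge bookkeeping diverged from the grid pass");
    WindowCounts ev =
        gillespieWindow(cand, candD2, candIdxOf, stampOf, stamp, bridges,
                        bridgeD2, bridgeIdxOf, bound, freeR, kOnPair, kOff,
                        dt, rng);
    accBind += ev.nBind;
    accUnbind += ev.nUnbind;
    t += dt;

    const int nb = (int)bridges.size();
    if (nb == 0) {
      lastNcb = 0;
      if (terminateOnDetach) {
        status = "detached";
        record();
        break;
      }
      // continue-free: centre unchanged; rebinding possible next window
    } else {
      // bridgeD2 already holds the distance of every anchor to the frozen
      // centre (grid pass + event updates); find the exact region from the
      // anchors closest to the boundary, growing the candidate prefix until
      // the excluded anchors are certified irrelevant (their disks contain
      // the whole region)
      int m = std::min(nb, 32);
      auto desc = [&](int a, int b) { return bridgeD2[a] > bridgeD2[b]; };
      for (;;) {
        selIdx.resize(nb);
        for (int i = 0; i < nb; ++i) selIdx[i] = i;
        double dNext = -1.0;
        if (m < nb) {
          std::nth_element(selIdx.begin(), selIdx.begin() + m, selIdx.end(),
                           desc);
          double mx = 0.0;
          for (int i = m; i < nb; ++i) mx = std::max(mx, bridgeD2[selIdx[i]]);
          dNext = std::sqrt(mx);
        }
        std::sort(selIdx.begin(), selIdx.begin() + m, desc);
        ordLig.resize(m);
        dOrd.resize(m);
        for (int i = 0; i < m; ++i) {
          ordLig[i] = bridges[selIdx[i]];
          dOrd[i] = std::sqrt(bridgeD2[selIdx[i]]);
        }
        if (computeRegion(&ligX[0], &ligY[0], ordLig, dOrd, dNext, R, cx, cy,
                          reg))
          break;
        m = std::min(nb, 2 * m);
      }
      double nx_, ny_;
      sampleRegion(&ligX[0], &ligY[0], ordLig, R, cx, cy, reg, rng, nx_, ny_);
      cx = nx_;
      cy = ny_;
      lastNcb = (int)(ordLig.size() == 1 ? 1 : reg.cons.size());
      // periodic full feasibility audit (cheap amortized)
      if ((w & 255L) == 0) {
        const double lim2 = R * R * (1.0 + 2e-9);
        for (int i = 0; i < nb; ++i) {
          const double dx = ligX[bridges[i]] - cx, dy = ligY[bridges[i]] - cy;
          if (dx * dx + dy * dy > lim2)
            stop("bridge anchor escaped the disk after a move: geometry bug");
        }
      }
    }
    if (cx - R < ext[0] || cx + R > ext[1] || cy - R < ext[2] ||
        cy + R > ext[3]) {
      status = "margin";
      record();
      break;
    }
    if (status == "ok" && (w % recordEvery == 0)) record();
    if (status != "ok") break;
  }

  const int nrow = (int)(rows.size() / 7);
  NumericMatrix traj(nrow, 7);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 7; ++c) traj(r, c) = rows[(size_t)r * 7 + c];
  colnames(traj) = CharacterVector::create("t_s", "x_nm", "y_nm", "n_b",
                                           "n_cb", "n_bind", "n_unbind");
  return List::create(_["traj"] = traj, _["status"] = status,
                      _["rng"] = "xoshiro256++/splitmix64");
}
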