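#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Water-fat swap resolution by seeded region growing.
//
// The highest-magnitude voxel seeds the first region with its
// lower-residual candidate (ties to the water-dominant one). The region
// then grows through the 6-connected frontier in descending magnitude
// order (a max-heap on magnitude, ties by linear index): each voxel picks
// the candidate whose between-echo phasor is closer to the mean phasor of
// its already-resolved 6-neighbours, so the selection follows the smooth
// off-resonance field. Voxels whose two candidate phasors (nearly)
// coincide — noise-degenerate double roots, where the choice is immaterial
// but the common phasor is unreliable — are flagged uninformative by the
// caller and never contribute to neighbour means. When the frontier is
// exhausted the next unvisited voxel (in global descending magnitude
// order, `order0`) seeds a new region: disconnected regions are resolved
// independently. Returns 1 or 2 per voxel (0 = below floor/unresolvable).
// [[Rcpp::export]]
IntegerVector resolve_region_grow_cpp(IntegerVector dim,
                                      IntegerVector order0,
                                      NumericVector p1re, NumericVector p1im,
                                      NumericVector p2re, NumericVector p2im,
                                      LogicalVector p1ok, LogicalVector p2ok,
                                      LogicalVector informative,
                                      NumericVector res1, NumericVector res2,
                                      NumericVector w1, NumericVector w2,
                                      NumericVector mag) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = p1re.size();
  IntegerVector choice(n, 0);
  std::vector<char> resolved(n, 0);
  std::vector<char> active(n, 0);    // above-floor voxels eligible at all
  std::vector<char> queued(n, 0);
  std::vector<char> has_phasor(n, 0);
  std::vector<double> cre(n, 0.0), cim(n, 0.0);

  for (R_xlen_t k = 0; k < order0.size(); ++k) active[order0[k]] = 1;

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  // full 26-neighbourhood offsets for the phasor mean
  int ex[26], ey[26], ez[26], ne = 0;
  for (int ax = -1; ax <= 1; ++ax)
    for (int ay = -1; ay <= 1; ++ay)
      for (int az = -1; az <= 1; ++az) {
        if (ax == 0 && ay == 0 && az == 0) continue;
        ex[ne] = ax; ey[ne] = ay; ez[ne] = az; ++ne;
      }

  typedef std::pair<double, R_xlen_t> Node;  // (magnitude, -index) max-heap
  auto cmp = [](const Node &a, const Node &b) {
    if (a.first != b.first) return a.first < b.first;
    return a.second < b.second;
  };
  std::priority_queue<Node, std::vector<Node>, decltype(cmp)> heap(cmp);
  std::queue<R_xlen_t> deferred;
  std::vector<char> was_deferred(n, 0);

  R_xlen_t next_seed = 0;
  const R_xlen_t n_order = order0.size();

  while (true) {
    R_xlen_t idx;
    if (!heap.empty()) {
      idx = -heap.top().second;
      heap.pop();
      if (resolved[idx]) continue;
    } else if (!deferred.empty()) {
      idx = deferred.front();
      deferred.pop();
      if (resolved[idx]) continue;
    } else {
      while (next_seed < n_order && resolved[order0[next_seed]]) ++next_seed;
      if (next_seed >= n_order) break;
      idx = order0[next_seed];
      ++next_seed;
    }

    const int x = idx % nx;
    const int y = (idx / nx) % ny;
    const int z = idx / (nx * ny);

    // magnitude-weighted mean phasor over the resolved 26-neighbourhood:
    // wider and weighted so single unreliable neighbours cannot flip the
    // decision at the growth frontier
    double mre = 0.0, mim = 0.0;
    for (int j = 0; j < ne; ++j) {
      const int xx = x + ex[j], yy = y + ey[j], zz = z + ez[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (has_phasor[nb]) {
        mre += mag[nb] * cre[nb];
        mim += mag[nb] * cim[nb];
      }
    }

    const bool ok1 = p1ok[idx], ok2 = p2ok[idx];
    int pick = 0;
    if (!ok1 && !ok2) {
      resolved[idx] = 1;  // zero-signal voxel: visited, no phasor, no choice
      continue;
    } else if (ok1 && !ok2) {
      pick = 1;
    } else if (!ok1 && ok2) {
      pick = 2;
    } else if (mre != 0.0 || mim != 0.0) {
      // unit candidates: closest to the neighbour mean phasor == largest
      // real inner product with it
      const double d1 = mre * p1re[idx] + mim * p1im[idx];
      const double d2 = mre * p2re[idx] + mim * p2im[idx];
      pick = (d1 >= d2) ? 1 : 2;
    } else if (queued[idx] && !was_deferred[idx]) {
      // reached by growth but no informative neighbour resolved yet (the
      // pusher was phasor-degenerate): retry once the region has grown,
      // instead of guessing and poisoning everything downstream
      was_deferred[idx] = 1;
      deferred.push(idx);
      continue;
    } else {
      // region seed (or no informative neighbour): both candidates usually
      // fit the magnitudes exactly (residuals at rounding level), so compare
      // with a magnitude-relative tolerance and prefer the water-dominant
      // candidate on a tie
      const double tol = 1e-6 * (mag[idx] + 1e-300);
      if (res1[idx] < res2[idx] - tol) pick = 1;
      else if (res2[idx] < res1[idx] - tol) pick = 2;
      else pick = (w1[idx] >= w2[idx]) ? 1 : 2;
    }

    choice[idx] = pick;
    resolved[idx] = 1;
    if (informative[idx]) {
      has_phasor[idx] = 1;
      cre[idx] = (pick == 1) ? p1re[idx] : p2re[idx];
      cim[idx] = (pick == 1) ? p1im[idx] : p2im[idx];
    }

    for (int j = 0; j < 6; ++j) {
      const int xx = x + dx[j], yy = y + dy[j], zz = z + dz[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (active[nb] && !resolved[nb] && !queued[nb]) {
        heap.push(Node(mag[nb], -nb));
        queued[nb] = 1;
      }
    }
  }
  return choice;
}
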