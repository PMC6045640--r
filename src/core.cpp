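#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids are R arrays in column-major order, dim = (nx, ny, nz).
// Linear index: idx = i + nx*(j + ny*k), 0-based here, 1-based at the R surface.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// Neighbourhood offset tables. connectivity: 6 (faces), 18 (faces+edges),
// 26 (full). For 2D planes pass nz = 1; 26 then degenerates to 8-connectivity
// and 6 to 4-connectivity.
static void neighbour_offsets(int connectivity, std::vector<int>& di,
                              std::vector<int>& dj, std::vector<int>& dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int k = v / (nx * ny);
      int r = v - k * nx * ny;
      int j = r / nx;
      int i = r - j * nx;
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
      }
    }
  }
  return labels;
}

// Separable 1-D convolution along one axis (axis: 1 = x, 2 = y, 3 = z).
// pad 0: zero padding; pad 1: replicate edge values.
// [[Rcpp::export(name = ".convolve_axis_cpp")]]
NumericVector convolve_axis_cpp(NumericVector arr, IntegerVector dims, int axis,
                                NumericVector kernel, int pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array length does not match dims");
  int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  int hw = kl / 2;
  NumericVector out(n);
  int len = (axis == 1) ? nx : (axis == 2 ? ny : nz);
  long stride = (axis == 1) ? 1 : (axis == 2 ? nx : (long)nx * ny);
  // iterate over all lines along `axis`
  for (int k = 0; k < (axis == 3 ? 1 : nz); ++k) {
    for (int j = 0; j < (axis == 2 ? 1 : ny); ++j) {
      for (int i = 0; i < (axis == 1 ? 1 : nx); ++i) {
        long base = i + (long)nx * (j + (long)ny * k);
        for (int p = 0; p < len; ++p) {
          double acc = 0.0;
          for (int t = -hw; t <= hw; ++t) {
            int q = p + t;
            if (q < 0) { if (pad == 0) continue; q = 0; }
            if (q >= len) { if (pad == 0) continue; q = len - 1; }
            acc += arr[base + (long)q * stride] * kernel[t + hw];
          }
          out[base + (long)p * stride] = acc;
        }
      }
    }
  }
  return out;
}

// Morphological dilation by an arbitrary offset set (rows of `offsets`: di,dj,dk).
// [[Rcpp::export(name = ".dilate_offsets_cpp")]]
LogicalVector dilate_offsets_cpp(LogicalVector mask, IntegerVector dims,
                                 IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int k = s / ((long)nx * ny);
    long r = s - (long)k * nx * ny;
    int j = r / nx;
    int i = r - (long)j * nx;
    for (int t = 0; t < offsets.nrow(); ++t) {
      int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      out[lin(ii, jj, kk, nx, ny)] = 1;
    }
  }
  return out;
}

// Erosion by an offset set; voxels whose offset neighbourhood leaves the grid
// are eroded (background outside the volume).
// [[Rcpp::export(name = ".erode_offsets_cpp")]]
LogicalVector erode_offsets_cpp(LogicalVector mask, IntegerVector dims,
                                IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int k = s / ((long)nx * ny);
    long r = s - (long)k * nx * ny;
    int j = r / nx;
    int i = r - (long)j * nx;
    bool keep = true;
    for (int t = 0; t < offsets.nrow() && keep; ++t) {
      int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) { keep = false; break; }
      if (!mask[lin(ii, jj, kk, nx, ny)]) keep = false;
    }
    if (keep) out[s] = 1;
  }
  return out;
}

// Directed Hausdorff term: sup over rows of A of inf over rows of B of
// Euclidean distance, with an early-exit inner loop.
// [[Rcpp::export(name = ".hausdorff_directed_cpp")]]
double hausdorff_directed_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  double best = 0.0;
  for (int a = 0; a < na; ++a) {
    double mind = R_PosInf;
    for (int b = 0; b < nb; ++b) {
      double acc = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = A(a, c) - B(b, c);
        acc += t * t;
      }
      if (acc < mind) {
        mind = acc;
        if (mind <= best) break; // cannot raise the sup
      }
    }
    if (mind > best && R_finite(mind)) best = mind;
  }
  return std::sqrt(best);
}

// Hill-climbing shrink of a masking surface toward the tumor boundary.
//
// An inward-moving front starts at the surface of `ms`. Front voxels are
// processed in descending order of physical distance to the seed. A front
// voxel v_i is removed (relabelled background) and the front advances to its
// inward neighbour v_j unless the joint stopping criterion freezes it:
// mean uptake increasing inward (fbar_j > fbar_i) and the Gaussian-filtered
// gradient magnitude no longer rising inward, expressed through the affinity
// phi = exp(-beta * (g_j - g_i)) >= tau for the uphill move (beta > 0).
// Frozen voxels and everything inward of them remain foreground.
//
// Status codes in the returned vector: 0 outside ms, 1 interior (never
// reached), 3 removed, 4 frozen. The final tumor mask is {1, 4}.
// [[Rcpp::export(name = ".hill_climb_cpp")]]
IntegerVector hill_climb_cpp(NumericVector fbar, NumericVector g,
                             IntegerVector dims, LogicalVector ms,
                             IntegerVector seed, NumericVector spacing,
                             double beta, double tau, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (beta <= 0 || tau <= 0) stop("beta and tau must be positive");
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  IntegerVector status(n, 0);
  long inside = 0;
  for (R_xlen_t s = 0; s < n; ++s) if (ms[s]) { status[s] = 1; ++inside; }
  if (inside < 2) stop("masking surface has fewer than 2 voxels");
  if (!ms[lin(si, sj, sk, nx, ny)]) stop("seed lies outside the masking surface");

  auto dist2 = [&](int i, int j, int k) {
    double a = (i - si) * sx, b = (j - sj) * sy, c = (k - sk) * sz;
    return a * a + b * b + c * c;
  };

  typedef std::pair<double, int> QE; // (distance^2, linear index)
  std::priority_queue<QE> pq;
  std::vector<char> queued(n, 0); // in-queue marker (status stays 1 until popped)

  // initial front: mask voxels with a face-adjacent background voxel or at the
  // volume border
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = lin(i, j, k, nx, ny);
        if (!status[v]) continue;
        bool front = false;
        const int fi[6] = {1,-1,0,0,0,0}, fj[6] = {0,0,1,-1,0,0}, fk[6] = {0,0,0,0,1,-1};
        for (int t = 0; t < 6; ++t) {
          int ii = i + fi[t], jj = j + fj[t], kk = k + fk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
              !status[lin(ii, jj, kk, nx, ny)]) { front = true; break; }
        }
        if (front) { pq.push(QE(dist2(i, j, k), v)); queued[v] = 1; }
      }

  long remaining = inside;
  int seedlin = lin(si, sj, sk, nx, ny);
  while (!pq.empty()) {
    int v = pq.top().second; pq.pop();
    if (status[v] != 1 || !queued[v]) continue; // stale entry
    queued[v] = 0;
    if (v == seedlin) { status[v] = 4; continue; } // the seed is never removed
    int k = v / (nx * ny);
    int r = v - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    // inward neighbour: in-mask neighbour minimising distance to seed,
    // ties broken by higher mean uptake, then by linear index
    int best = -1;
    double bestd = R_PosInf, bestf = -R_PosInf;
    for (size_t t = 0; t < di.size(); ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int w = lin(ii, jj, kk, nx, ny);
      if (status[w] != 1 && status[w] != 4) continue;
      double d2 = dist2(ii, jj, kk);
      if (d2 < bestd - 1e-12 ||
          (std::abs(d2 - bestd) <= 1e-12 &&
           (fbar[w] > bestf || (fbar[w] == bestf && (best < 0 || w < best))))) {
        bestd = d2; bestf = fbar[w]; best = w;
      }
    }
    bool freeze = false;
    if (best >= 0 && fbar[best] > fbar[v]) {
      // look one step ahead: the inward neighbour of v_j. The front voxel
      // freezes when the NEXT inward move would no longer climb the smoothed
      // gradient-magnitude ridge, leaving the frozen contour on the outer
      // shoulder of the boundary ridge.
      int bk = v / (nx * ny);
      int w = best;
      int wk = w / (nx * ny);
      int wr = w - wk * nx * ny;
      int wj = wr / nx;
      int wi = wr - wj * nx;
      int nxt2 = -1;
      double nd = R_PosInf, nf = -R_PosInf;
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = wi + di[t], jj = wj + dj[t], kk = wk + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int u = lin(ii, jj, kk, nx, ny);
        if (u == v) continue;
        if (status[u] != 1 && status[u] != 4) continue;
        double d2 = dist2(ii, jj, kk);
        if (d2 < nd - 1e-12 ||
            (std::abs(d2 - nd) <= 1e-12 &&
             (fbar[u] > nf || (fbar[u] == nf && (nxt2 < 0 || u < nxt2))))) {
          nd = d2; nf = fbar[u]; nxt2 = u;
        }
      }
      double gfrom = g[best];
      double gto = (nxt2 >= 0) ? g[nxt2] : g[best];
      double ex = -beta * (gto - gfrom);
      if (ex > 700) ex = 700; else if (ex < -700) ex = -700;
      freeze = (std::exp(ex) >= tau);
      (void)bk;
    }
    if (freeze) {
      status[v] = 4;
    } else {
      status[v] = 3;
      --remaining;
      if (remaining < 2) stop("no boundary found; check seed/3D-MS");
      for (size_t t = 0; t < di.size(); ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int w = lin(ii, jj, kk, nx, ny);
        if (status[w] == 1 && !queued[w]) { pq.push(QE(dist2(ii, jj, kk), w)); queued[w] = 1; }
      }
    }
  }
  return status;
}
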