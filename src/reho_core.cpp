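#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Mid-rank a segment x[s..s+n) into out, returning the tie-correction term
// T = sum over tie groups of (t^3 - t).
static double midrank(const double *x, int n, double *out,
                      std::vector<int> &ord) {
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double tie = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average of 1-based ranks i+1..j+1
    for (int k = i; k <= j; ++k) out[ord[k]] = r;
    int t = j - i + 1;
    if (t > 1) tie += (double)t * t * t - t;
    i = j + 1;
  }
  return tie;
}

// Kendall's W of each voxel's neighbourhood within each sliding window.
//
// ts:     V x T matrix, one row per in-mask voxel.
// nbr:    list of V integer vectors; 1-based row indices of the in-mask
//         neighbours of each voxel (self included).
// starts: 1-based window start indices.
// len:    window length (time points per window).
//
// Returns a V x n_windows matrix of concordance values. A neighbourhood of
// fewer than two voxels, or one in which every series is constant, yields 0.
// [[Rcpp::export]]
NumericMatrix cpp_windowed_reho(const NumericMatrix &ts, const List &nbr,
                                const IntegerVector &starts, int len) {
  const int V = ts.nrow();
  const int T = ts.ncol();
  const int W = starts.size();
  if (len < 2) stop("window length must be at least 2");
  if (nbr.size() != V) stop("neighbour list length must match voxel count");

  NumericMatrix out(V, W);
  std::vector<double> ranks((size_t)V * len);
  std::vector<double> tiecor(V);
  std::vector<double> seg(len);
  std::vector<int> ord;
  std::vector<double> rsum(len);

  // pre-extract neighbour indices (0-based)
  std::vector<std::vector<int>> nb(V);
  for (int v = 0; v < V; ++v) {
    IntegerVector iv = nbr[v];
    nb[v].assign(iv.begin(), iv.end());
    for (size_t k = 0; k < nb[v].size(); ++k) {
      nb[v][k] -= 1;
      if (nb[v][k] < 0 || nb[v][k] >= V) stop("neighbour index out of range");
    }
  }

  const double n = (double)len;
  const double n3n = n * n * n - n;

  for (int w = 0; w < W; ++w) {
    const int s = starts[w] - 1;
    if (s < 0 || s + len > T) stop("window exceeds series length");
    // rank every voxel's segment once per window
    for (int v = 0; v < V; ++v) {
      for (int i = 0; i < len; ++i) seg[i] = ts(v, s + i);
      tiecor[v] = midrank(seg.data(), len, &ranks[(size_t)v * len], ord);
    }
    for (int v = 0; v < V; ++v) {
      const std::vector<int> &ids = nb[v];
      const int K = (int)ids.size();
      if (K < 2) { out(v, w) = 0.0; continue; }
      std::fill(rsum.begin(), rsum.end(), 0.0);
      double tsum = 0.0;
      for (int k = 0; k < K; ++k) {
        const double *rv = &ranks[(size_t)ids[k] * len];
        for (int i = 0; i < len; ++i) rsum[i] += rv[i];
        tsum += tiecor[ids[k]];
      }
      const double rbar = K * (n + 1.0) / 2.0;
      double S = 0.0;
      for (int i = 0; i < len; ++i) {
        const double d = rsum[i] - rbar;
        S += d * d;
      }
      const double denom = (double)K * K * n3n - (double)K * tsum;
      out(v, w) = denom > 0.0 ? 12.0 * S / denom : 0.0;
    }
  }
  return out;
}

// Width-3 running sum along one axis of a 3D array (zero beyond the grid
// edge), applied in place via a scratch buffer.
static void boxsum_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, std::vector<double> &tmp) {
  tmp = a;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride;
  int len;
  if (axis == 0) { stride = sx; len = nx; }
  else if (axis == 1) { stride = sy; len = ny; }
  else { stride = sz; len = nz; }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int pos = (axis == 0) ? x : (axis == 1 ? y : z);
        R_xlen_t i = x * sx + y * sy + z * sz;
        double s = tmp[i];
        if (pos > 0) s += tmp[i - stride];
        if (pos < len - 1) s += tmp[i + stride];
        a[i] = s;
      }
}

static void boxsum3(std::vector<double> &a, int nx, int ny, int nz,
                    std::vector<double> &tmp) {
  boxsum_axis(a, nx, ny, nz, 0, tmp);
  boxsum_axis(a, nx, ny, nz, 1, tmp);
  boxsum_axis(a, nx, ny, nz, 2, tmp);
}

// Fast 27-neighbourhood windowed Kendall's W over a masked 4D volume.
// Neighbourhood rank sums are separable 3x3x3 box sums of the per-voxel
// rank images, so the cost per window is O(V * n) rather than O(V * n * 27).
// Returns a list: `w` (V_grid x n_windows matrix, 0 off-mask) and `K`
// (in-mask neighbour count per voxel).
// [[Rcpp::export]]
List cpp_dreho27(const NumericVector &data, const IntegerVector &dims,
                 const LogicalVector &mask, const IntegerVector &starts,
                 int len) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  const int W = starts.size();
  if (len < 2) stop("window length must be at least 2");

  // neighbour count: box sum of the mask indicator
  std::vector<double> kbuf(V), tmp(V);
  for (R_xlen_t v = 0; v < V; ++v) kbuf[v] = mask[v] ? 1.0 : 0.0;
  boxsum3(kbuf, nx, ny, nz, tmp);
  IntegerVector K(V);
  for (R_xlen_t v = 0; v < V; ++v) K[v] = mask[v] ? (int)(kbuf[v] + 0.5) : 0;

  NumericMatrix out(V, W);
  const double n = (double)len;
  const double n3n = n * n * n - n;

  std::vector<double> seg(len), rk(len);
  std::vector<int> ord;
  // rank images, timepoint-major: ranks[i*V + v]
  std::vector<double> ranks((size_t)V * len, 0.0);
  std::vector<double> ties(V, 0.0), tsum(V);
  std::vector<double> acc1(V), acc2(V), slice(V);

  for (int w = 0; w < W; ++w) {
    const int s = starts[w] - 1;
    if (s < 0 || s + len > nt) stop("window exceeds series length");
    for (R_xlen_t v = 0; v < V; ++v) {
      if (!mask[v]) continue;
      for (int i = 0; i < len; ++i) seg[i] = data[(R_xlen_t)(s + i) * V + v];
      ties[v] = midrank(seg.data(), len, rk.data(), ord);
      for (int i = 0; i < len; ++i) ranks[(size_t)i * V + v] = rk[i];
    }
    std::fill(acc1.begin(), acc1.end(), 0.0);
    std::fill(acc2.begin(), acc2.end(), 0.0);
    for (int i = 0; i < len; ++i) {
      std::copy(ranks.begin() + (size_t)i * V,
                ranks.begin() + (size_t)(i + 1) * V, slice.begin());
      boxsum3(slice, nx, ny, nz, tmp);
      for (R_xlen_t v = 0; v < V; ++v) {
        acc1[v] += slice[v];
        acc2[v] += slice[v] * slice[v];
      }
    }
    tsum = ties;
    boxsum3(tsum, nx, ny, nz, tmp);
    for (R_xlen_t v = 0; v < V; ++v) {
      if (!mask[v] || K[v] < 2) { out(v, w) = 0.0; continue; }
      const double S = acc2[v] - acc1[v] * acc1[v] / n;
      const double denom = (double)K[v] * K[v] * n3n - K[v] * tsum[v];
      out(v, w) = denom > 0.0 ? 12.0 * S / denom : 0.0;
    }
  }
  return List::create(_["w"] = out, _["K"] = K);
}

// Connected-component labelling of a 3D logical array under 6/18/26
// connectivity. Returns an integer array of labels (0 = background),
// components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector &img,
                                   const IntegerVector &dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (img.size() != n) stop("image size does not match dims");

  // neighbourhood offsets
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }

  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!img[i] || lab[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (img[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
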