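// SLIC superpixels for grayscale images (Achanta et al.'s k-means formulation
// restricted to one intensity channel). Deterministic: grid seeding, gradient
// perturbation, fixed iteration count, connectivity enforcement.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

// img: height x width, any numeric range (distances use the range as-is, so
// callers should pass [0,255]-scaled intensities for a meaningful compactness).
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix img, int k, double compactness, int max_iter) {
  int H = img.nrow(), W = img.ncol();
  int N = H * W;
  double S = std::sqrt((double)N / k);     // grid interval
  if (S < 1.0) S = 1.0;

  // seed on a regular grid
  std::vector<double> cy_, cx_, cl_;
  int ny = std::max(1, (int)std::floor(H / S + 0.5));
  int nx = std::max(1, (int)std::floor(W / S + 0.5));
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double y = (j + 0.5) * H / ny, x = (i + 0.5) * W / nx;
      int yi = std::min(H - 1, std::max(0, (int)y));
      int xi = std::min(W - 1, std::max(0, (int)x));
      // perturb to lowest-gradient pixel in the 3x3 neighborhood
      double best = 1e300; int by = yi, bx = xi;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int y2 = yi + dy, x2 = xi + dx;
          if (y2 < 1 || y2 >= H - 1 || x2 < 1 || x2 >= W - 1) continue;
          double gx = img(y2, x2 + 1) - img(y2, x2 - 1);
          double gy = img(y2 + 1, x2) - img(y2 - 1, x2);
          double g = gx * gx + gy * gy;
          if (g < best) { best = g; by = y2; bx = x2; }
        }
      }
      cy_.push_back(by); cx_.push_back(bx); cl_.push_back(img(by, bx));
    }
  }
  int K = (int)cy_.size();
  std::vector<int> label(N, -1);
  std::vector<double> dist(N);
  double invS2 = (compactness * compactness) / (S * S);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), 1e300);
    for (int c = 0; c < K; ++c) {
      int y0 = std::max(0, (int)(cy_[c] - 2 * S)), y1 = std::min(H - 1, (int)(cy_[c] + 2 * S));
      int x0 = std::max(0, (int)(cx_[c] - 2 * S)), x1 = std::min(W - 1, (int)(cx_[c] + 2 * S));
      for (int y = y0; y <= y1; ++y) {
        for (int x = x0; x <= x1; ++x) {
          double dc = img(y, x) - cl_[c];
          double ds = (y - cy_[c]) * (y - cy_[c]) + (x - cx_[c]) * (x - cx_[c]);
          double d = dc * dc + ds * invS2;
          int idx = y * W + x;
          if (d < dist[idx]) { dist[idx] = d; label[idx] = c; }
        }
      }
    }
    // update centers
    std::vector<double> sy(K, 0), sx(K, 0), sl(K, 0), cnt(K, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int c = label[y * W + x];
        if (c < 0) continue;
        sy[c] += y; sx[c] += x; sl[c] += img(y, x); cnt[c] += 1;
      }
    for (int c = 0; c < K; ++c) {
      if (cnt[c] > 0) { cy_[c] = sy[c] / cnt[c]; cx_[c] = sx[c] / cnt[c]; cl_[c] = sl[c] / cnt[c]; }
    }
  }
  // orphans (never assigned: possible if K*4S^2 windows miss a pixel) -> nearest center
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int idx = y * W + x;
      if (label[idx] >= 0) continue;
      double best = 1e300; int bc = 0;
      for (int c = 0; c < K; ++c) {
        double ds = (y - cy_[c]) * (y - cy_[c]) + (x - cx_[c]) * (x - cx_[c]);
        if (ds < best) { best = ds; bc = c; }
      }
      label[idx] = bc;
    }

  // enforce connectivity: relabel connected components; absorb components
  // smaller than N/(4K) into an adjacent component.
  std::vector<int> comp(N, -1);
  std::vector<int> comp_label, comp_size, comp_nbr;
  int ncomp = 0;
  int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  for (int start = 0; start < N; ++start) {
    if (comp[start] >= 0) continue;
    std::queue<int> q;
    q.push(start); comp[start] = ncomp;
    int size = 0, nbr = -1;
    while (!q.empty()) {
      int idx = q.front(); q.pop();
      ++size;
      int y = idx / W, x = idx % W;
      for (int d = 0; d < 4; ++d) {
        int y2 = y + dy4[d], x2 = x + dx4[d];
        if (y2 < 0 || y2 >= H || x2 < 0 || x2 >= W) continue;
        int idx2 = y2 * W + x2;
        if (label[idx2] == label[start]) {
          if (comp[idx2] < 0) { comp[idx2] = ncomp; q.push(idx2); }
        } else if (comp[idx2] >= 0 && comp[idx2] != ncomp) {
          nbr = comp[idx2];
        }
      }
    }
    comp_label.push_back(label[start]);
    comp_size.push_back(size);
    comp_nbr.push_back(nbr);
    ++ncomp;
  }
  int min_size = std::max(1, N / (4 * K));
  std::vector<int> final_label(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    if (comp_size[c] < min_size && comp_nbr[c] >= 0)
      final_label[c] = comp_label[comp_nbr[c]];
    else
      final_label[c] = comp_label[c];
  }
  // compact label ids to 1..K' in scan order
  std::vector<int> remap(K, 0);
  int next_id = 0;
  IntegerMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int l = final_label[comp[y * W + x]];
      if (remap[l] == 0) remap[l] = ++next_id;
      out(y, x) = remap[l];
    }
  return out;
}
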