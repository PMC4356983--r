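// Low-level raster primitives for plate image analysis.
// Matrices are column-major (R layout); pixel (r, c) = x[r + c * nrow].
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <cstring>
using namespace Rcpp;

static inline int idx(int r, int c, int nr) { return r + c * nr; }

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  qr.reserve(1024); qc.reserve(1024);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      qr.clear(); qc.clear();
      qr.push_back(r); qc.push_back(c);
      for (size_t h = 0; h < qr.size(); ++h) {
        const int rr = qr[h], cc = qc[h];
        for (int k = 0; k < nnb; ++k) {
          const int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            qr.push_back(r2); qc.push_back(c2);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance of each foreground pixel to the nearest background pixel.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  const double INF = 1e18;
  NumericMatrix sq(nr, nc);
  // pass 1: along rows (within each column)
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = fg(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) sq(r, c) = d[r];
  }
  // pass 2: along columns (within each row)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = sq(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) sq(r, c) = std::sqrt(d[c]);
  }
  return sq;
}

// ---------------------------------------------------------------------------
// Seeded watershed / region growing: Meyer flooding in increasing elevation,
// restricted to mask. Seed pixels keep their labels; ties broken FIFO.
struct WsNode {
  double h;
  long order;
  int pix;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.h != b.h) return a.h > b.h;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elevation, const IntegerMatrix& seeds,
                            const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = elevation.nrow(), nc = elevation.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) lab(r, c) = seeds(r, c);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) == 0) continue;
      for (int k = 0; k < nnb; ++k) {
        const int r2 = r + dr8[k], c2 = c + dc8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) && lab(r2, c2) == 0)
          pq.push(WsNode{elevation(r2, c2), order++, idx(r2, c2, nr), lab(r, c)});
      }
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    const int r = nd.pix % nr, c = nd.pix / nr;
    if (lab(r, c) != 0) continue;
    lab(r, c) = nd.lab;
    for (int k = 0; k < nnb; ++k) {
      const int r2 = r + dr8[k], c2 = c + dc8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0)
        pq.push(WsNode{elevation(r2, c2), order++, idx(r2, c2, nr), nd.lab});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 2D median filter, square window of half-width `radius`, window clipped at
// image borders. Values are quantised to 0.5-count bins (two-level histogram);
// exact for integer count data, <= 0.25 counts error otherwise.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int NBIN = 131072, NCOARSE = 512, FINE = 256; // NBIN = NCOARSE * FINE
  NumericMatrix out(nr, nc);
  IntegerMatrix q(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c) * 2.0;
      int b = (int)std::lround(v);
      if (b < 0) b = 0;
      if (b >= NBIN) b = NBIN - 1;
      q(r, c) = b;
    }
  std::vector<int> coarse(NCOARSE), fine(NBIN);
  for (int r = 0; r < nr; ++r) {
    const int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
    std::fill(coarse.begin(), coarse.end(), 0);
    std::fill(fine.begin(), fine.end(), 0);
    int count = 0;
    const int c1init = std::min(nc - 1, radius);
    for (int cc = 0; cc <= c1init; ++cc)
      for (int rr = r0; rr <= r1; ++rr) {
        const int b = q(rr, cc);
        ++fine[b]; ++coarse[b / FINE]; ++count;
      }
    for (int c = 0; c < nc; ++c) {
      if (c > 0) {
        const int cadd = c + radius, cdel = c - radius - 1;
        if (cadd < nc)
          for (int rr = r0; rr <= r1; ++rr) {
            const int b = q(rr, cadd);
            ++fine[b]; ++coarse[b / FINE]; ++count;
          }
        if (cdel >= 0)
          for (int rr = r0; rr <= r1; ++rr) {
            const int b = q(rr, cdel);
            --fine[b]; --coarse[b / FINE]; --count;
          }
      }
      // lower median: k-th smallest with k = (count + 1) / 2
      int k = (count + 1) / 2, acc = 0, cb = 0;
      while (acc + coarse[cb] < k) { acc += coarse[cb]; ++cb; }
      int b = cb * FINE;
      while (acc + fine[b] < k) { acc += fine[b]; ++b; }
      out(r, c) = b / 2.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflective boundary, kernel radius ceil(3*sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) a += k[i + rad] * img(reflect(r + i, nr), c);
      tmp(r, c) = a;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double a = 0;
      for (int i = -rad; i <= rad; ++i) a += k[i + rad] * tmp(r, reflect(c + i, nc));
      out(r, c) = a;
    }
  return out;
}

// ---------------------------------------------------------------------------
// 3x3 convolution with reflective boundary (Laplacian etc.).
// [[Rcpp::export]]
NumericMatrix cpp_convolve3(const NumericMatrix& img, const NumericMatrix& kern) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  auto reflect = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double a = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          a += kern(dr + 1, dc + 1) * img(reflect(r + dr, nr), reflect(c + dc, nc));
      out(r, c) = a;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local maxima within a square neighbourhood of half-width `radius`,
// above `threshold`; plateaus yield every plateau pixel (merged downstream).
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(const NumericMatrix& img, int radius, double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v = img(r, c);
      if (v <= threshold) { out(r, c) = false; continue; }
      bool is_max = true;
      const int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      const int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
      for (int cc = c0; cc <= c1 && is_max; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          if (img(rr, cc) > v) { is_max = false; break; }
      out(r, c) = is_max;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pixel-wise median across a list of equally sized matrices.
// [[Rcpp::export]]
NumericMatrix cpp_pixelwise_median(const List& imgs) {
  const int n = imgs.size();
  NumericMatrix first = imgs[0];
  const int nr = first.nrow(), nc = first.ncol();
  NumericMatrix out(nr, nc);
  std::vector<const double*> ptr(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = imgs[i];
    if (m.nrow() != nr || m.ncol() != nc) stop("image shape mismatch");
    ptr[i] = REAL(m);
  }
  std::vector<double> buf(n);
  const int npix = nr * nc;
  for (int p = 0; p < npix; ++p) {
    for (int i = 0; i < n; ++i) buf[i] = ptr[i][p];
    std::nth_element(buf.begin(), buf.begin() + (n - 1) / 2, buf.end());
    double med = buf[(n - 1) / 2];
    if (n % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      med = (med + buf[n / 2]) / 2.0;
    }
    out[p] = med;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-label geometry: area, exposed 4-neighbour edge count, and count of
// boundary pixels (pixels with a 4-neighbour of another label / background).
// [[Rcpp::export]]
NumericMatrix cpp_region_geometry(const IntegerMatrix& lab, int nlab) {
  NumericMatrix out(nlab, 3);
  const int nr = lab.nrow(), nc = lab.ncol();
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l <= 0 || l > nlab) continue;
      out(l - 1, 0) += 1;
      bool boundary = false;
      for (int k = 0; k < 4; ++k) {
        const int r2 = r + dr[k], c2 = c + dc[k];
        const int l2 = (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) ? 0 : lab(r2, c2);
        if (l2 != l) { out(l - 1, 1) += 1; boundary = true; }
      }
      if (boundary) out(l - 1, 2) += 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-label sums of a value raster (fluorescence integration workhorse).
// [[Rcpp::export]]
NumericVector cpp_region_sums(const IntegerMatrix& lab, const NumericMatrix& values, int nlab) {
  if (lab.nrow() != values.nrow() || lab.ncol() != values.ncol()) stop("shape mismatch");
  NumericVector out(nlab);
  const int npix = lab.nrow() * lab.ncol();
  for (int p = 0; p < npix; ++p) {
    const int l = lab[p];
    if (l > 0 && l <= nlab) out[l - 1] += values[p];
  }
  return out;
}
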