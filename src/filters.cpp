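#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pixel neighbourhood helpers. Images are R matrices (column-major);
// a linear index i maps to row i % nr, col i / nr.

static inline int n_neighbors(int idx, int nr, int nc, bool eight, int* out) {
  int r = idx % nr, c = idx / nr, k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      if (dr == 0 && dc == 0) continue;
      if (!eight && dr != 0 && dc != 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      out[k++] = rr + cc * nr;
    }
  }
  return k;
}

// Regional minima: connected plateaus (8-connected, equal value) whose
// every outside neighbour is strictly greater. Returns an integer matrix
// labelling each minimum plateau 1..k (0 elsewhere). Labels are assigned
// in row-major order of the first pixel reached, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<int> state(n, 0);  // 0 unvisited, 1 in current plateau, 2 done
  int nb[8];
  int next_label = 0;
  // row-major scan: iterate rows outer so plateau ids follow reading order
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int start = r + c * nr;
      if (state[start] == 2) continue;
      double v = img[start];
      // flood the equal-value plateau containing start
      std::vector<int> plateau;
      std::queue<int> q;
      q.push(start);
      state[start] = 1;
      bool is_min = true;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        plateau.push_back(p);
        int k = n_neighbors(p, nr, nc, true, nb);
        for (int j = 0; j < k; ++j) {
          int u = nb[j];
          double w = img[u];
          if (w < v) is_min = false;
          else if (w == v && state[u] == 0) { state[u] = 1; q.push(u); }
        }
      }
      if (is_min) ++next_label;
      for (size_t j = 0; j < plateau.size(); ++j) {
        state[plateau[j]] = 2;
        if (is_min) lab[plateau[j]] = next_label;
      }
    }
  }
  return lab;
}

// Marker-controlled watershed (Meyer flooding). Seeds are positive integer
// markers; flooding is 8-connected and ordered by (pixel value, discovery
// order): among equal values the pixel queued first is flooded first, so
// plateaus (which median-filtered surfaces produce in abundance) are split
// where the wavefronts meet rather than swept in raster order. The rule is
// deterministic. A pixel first reached from regions of two or more distinct
// labels becomes a watershed line (label 0).
struct QEntry {
  double v; long long ord; int idx;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.v != b.v) return a.v > b.v;          // min-heap on value
    return a.ord > b.ord;                       // then discovery (FIFO) order
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix img, IntegerMatrix seeds) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("seed matrix dimensions must match image");
  IntegerMatrix lab(nr, nc);
  std::vector<char> queued(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  int nb[8];
  long long order = 0;  // FIFO rank among equal values
  int n_seeded = 0;
  for (int i = 0; i < n; ++i) {
    if (seeds[i] > 0) { lab[i] = seeds[i]; queued[i] = 1; ++n_seeded; }
  }
  if (n_seeded == 0) stop("watershed requires at least one seed pixel");
  // initialise the frontier with unlabelled neighbours of seed regions
  for (int i = 0; i < n; ++i) {
    if (lab[i] == 0) continue;
    int k = n_neighbors(i, nr, nc, true, nb);
    for (int j = 0; j < k; ++j) {
      int u = nb[j];
      if (!queued[u]) { queued[u] = 1; pq.push({img[u], order++, u}); }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int p = e.idx;
    // label from already-labelled neighbours; pixels are only ever queued
    // from a labelled neighbour, so found >= 1 on pop
    int k = n_neighbors(p, nr, nc, true, nb);
    int found = 0; bool conflict = false;
    for (int j = 0; j < k; ++j) {
      int l = lab[nb[j]];
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (conflict) {
      lab[p] = 0;  // watershed line; lines do not extend the flood
      continue;
    }
    lab[p] = found;
    for (int j = 0; j < k; ++j) {
      int u = nb[j];
      if (!queued[u]) {
        queued[u] = 1;
        pq.push({img[u], order++, u});
      }
    }
  }
  // pixels never reached (walled off by lines) keep label 0 = boundary
  return lab;
}

// Median filter with a size x size square window, truncated at image borders.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int size) {
  if (size < 1 || size % 2 == 0) stop("median filter size must be odd and >= 1");
  int nr = img.nrow(), nc = img.ncol(), h = size / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)size * size);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
      int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          buf.push_back(img(rr, cc));
      size_t m = buf.size();
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Grayscale erosion / dilation with a flat disc of the given radius,
// truncated at borders. Used for rolling-ball style background estimation
// (opening = erosion then dilation).
static NumericMatrix disc_rank(NumericMatrix img, double radius, bool take_min) {
  int nr = img.nrow(), nc = img.ncol();
  int h = (int)std::floor(radius);
  std::vector<std::pair<int,int>> offs;
  for (int dc = -h; dc <= h; ++dc)
    for (int dr = -h; dr <= h; ++dr)
      if ((double)dr * dr + (double)dc * dc <= radius * radius + 1e-9)
        offs.push_back({dr, dc});
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = take_min ? R_PosInf : R_NegInf;
      for (size_t j = 0; j < offs.size(); ++j) {
        int rr = r + offs[j].first, cc = c + offs[j].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc);
        if (take_min ? (v < best) : (v > best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_erode(NumericMatrix img, double radius) {
  return disc_rank(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_dilate(NumericMatrix img, double radius) {
  return disc_rank(img, radius, false);
}
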