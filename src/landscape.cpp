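#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}
static void uf_union(std::vector<int>& p, int a, int b) {
  a = uf_find(p, a); b = uf_find(p, b);
  if (a != b) p[b < a ? a : b] = (b < a ? b : a);  // keep the smaller root
}

// Maximum number of internal (shared) edges among m cells packed on a
// square lattice: the largest-integer-square construction.
static double max_like_adj(double m) {
  if (m <= 1) return 0.0;
  double s = std::floor(std::sqrt(m));
  double rem = m - s * s;
  double base = 2.0 * s * (s - 1.0);
  if (rem == 0) return base;
  if (rem <= s) return base + 2.0 * rem - 1.0;
  return base + 2.0 * rem - 2.0;
}

// Label maximal connected same-class regions of a masked categorical grid.
// Patch ids are 1-based in first-touch (row-major reading) order.
// [[Rcpp::export]]
List label_patches_cpp(NumericMatrix vals, LogicalMatrix mask, int connectivity) {
  int nr = vals.nrow(), nc = vals.ncol(), n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto idx = [nr](int r, int c) { return c * nr + r; };  // column-major like R
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double v = vals(r, c);
      if (r > 0 && mask(r - 1, c) && vals(r - 1, c) == v)
        uf_union(parent, idx(r, c), idx(r - 1, c));
      if (c > 0 && mask(r, c - 1) && vals(r, c - 1) == v)
        uf_union(parent, idx(r, c), idx(r, c - 1));
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1) && vals(r - 1, c - 1) == v)
          uf_union(parent, idx(r, c), idx(r - 1, c - 1));
        if (r < nr - 1 && c > 0 && mask(r + 1, c - 1) && vals(r + 1, c - 1) == v)
          uf_union(parent, idx(r, c), idx(r + 1, c - 1));
      }
    }
  }
  IntegerMatrix labels(nr, nc);
  std::vector<int> root_id(n, 0);
  std::vector<double> patch_class;
  std::vector<int> patch_cells;
  int next_id = 0;
  for (int r = 0; r < nr; ++r) {        // row-major reading order for ids
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) { labels(r, c) = NA_INTEGER; continue; }
      int root = uf_find(parent, idx(r, c));
      if (root_id[root] == 0) {
        root_id[root] = ++next_id;
        patch_class.push_back(vals(r, c));
        patch_cells.push_back(0);
      }
      labels(r, c) = root_id[root];
      patch_cells[root_id[root] - 1]++;
    }
  }
  return List::create(_["labels"] = labels,
                      _["patch_class"] = NumericVector(patch_class.begin(), patch_class.end()),
                      _["patch_cells"] = IntegerVector(patch_cells.begin(), patch_cells.end()));
}

// Single-count like-adjacency (shared edges between same-class valid cells,
// rook neighbourhood) per class.
// [[Rcpp::export]]
List like_adjacency_cpp(NumericMatrix vals, LogicalMatrix mask) {
  int nr = vals.nrow(), nc = vals.ncol();
  std::map<double, double> g;
  std::map<double, double> cells;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double v = vals(r, c);
      cells[v] += 1.0;
      if (r + 1 < nr && mask(r + 1, c) && vals(r + 1, c) == v) g[v] += 1.0;
      if (c + 1 < nc && mask(r, c + 1) && vals(r, c + 1) == v) g[v] += 1.0;
    }
  int k = cells.size();
  NumericVector cls(k), adj(k), m(k);
  int i = 0;
  for (auto& kv : cells) {
    cls[i] = kv.first;
    m[i] = kv.second;
    adj[i] = g.count(kv.first) ? g[kv.first] : 0.0;
    ++i;
  }
  return List::create(_["class"] = cls, _["cells"] = m, _["adjacencies"] = adj);
}

// The five landscape-level metrics of a masked categorical buffer.
// Returns (np, lpi, ai, division, shdi); all NA when no valid cell.
static void metrics_core(const double* vals, const char* msk, int nr, int nc,
                         int connectivity, double* out) {
  int n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto at = [&](int r, int c) { return c * nr + r; };
  double total = 0.0;
  std::map<double, double> cls_cells, cls_adj;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = at(r, c);
      if (!msk[i]) continue;
      double v = vals[i];
      total += 1.0;
      cls_cells[v] += 1.0;
      if (r + 1 < nr && msk[at(r + 1, c)] && vals[at(r + 1, c)] == v) {
        cls_adj[v] += 1.0;
        uf_union(parent, i, at(r + 1, c));
      }
      if (c + 1 < nc && msk[at(r, c + 1)] && vals[at(r, c + 1)] == v)
        { cls_adj[v] += 1.0; uf_union(parent, i, at(r, c + 1)); }
      if (connectivity == 8) {
        if (r + 1 < nr && c + 1 < nc && msk[at(r + 1, c + 1)] &&
            vals[at(r + 1, c + 1)] == v)
          uf_union(parent, i, at(r + 1, c + 1));
        if (r > 0 && c + 1 < nc && msk[at(r - 1, c + 1)] &&
            vals[at(r - 1, c + 1)] == v)
          uf_union(parent, i, at(r - 1, c + 1));
      }
    }
  }
  if (total == 0.0) {
    for (int j = 0; j < 5; ++j) out[j] = NA_REAL;
    return;
  }
  std::map<int, double> comp_size;
  for (int i = 0; i < n; ++i)
    if (msk[i]) comp_size[uf_find(parent, i)] += 1.0;
  double np = comp_size.size(), maxp = 0.0, div_acc = 0.0;
  for (auto& kv : comp_size) {
    if (kv.second > maxp) maxp = kv.second;
    double f = kv.second / total;
    div_acc += f * f;
  }
  double shdi = 0.0, ai = 0.0;
  for (auto& kv : cls_cells) {
    double p = kv.second / total;
    if (p > 0) shdi -= p * std::log(p);
    double mx = max_like_adj(kv.second);
    if (mx > 0) {
      double gcc = cls_adj.count(kv.first) ? cls_adj[kv.first] : 0.0;
      ai += p * (gcc / mx) * 100.0;
    }
  }
  out[0] = np;
  out[1] = 100.0 * maxp / total;
  out[2] = ai;
  out[3] = 1.0 - div_acc;
  out[4] = shdi;
}

// [[Rcpp::export]]
NumericVector metrics_cpp(NumericMatrix vals, LogicalMatrix mask, int connectivity) {
  int nr = vals.nrow(), nc = vals.ncol(), n = nr * nc;
  std::vector<char> msk(n);
  for (int i = 0; i < n; ++i) msk[i] = mask[i] ? 1 : 0;
  NumericVector out(5);
  metrics_core(REAL(vals), msk.data(), nr, nc, connectivity, REAL(out));
  out.names() = CharacterVector::create("np", "lpi", "ai", "division", "shdi");
  return out;
}

// Moving-window metric surfaces: for every window position whose center
// lies on the stride lattice and whose window fits inside the grid, the
// five metrics of the window's valid cells. Everything else is NA.
// [[Rcpp::export]]
List moving_window_cpp(NumericMatrix vals, LogicalMatrix mask, int window,
                       int stride, int connectivity) {
  int nr = vals.nrow(), nc = vals.ncol();
  int half = window / 2;
  NumericMatrix np(nr, nc), lpi(nr, nc), ai(nr, nc), division(nr, nc), shdi(nr, nc);
  std::fill(np.begin(), np.end(), NA_REAL);
  std::fill(lpi.begin(), lpi.end(), NA_REAL);
  std::fill(ai.begin(), ai.end(), NA_REAL);
  std::fill(division.begin(), division.end(), NA_REAL);
  std::fill(shdi.begin(), shdi.end(), NA_REAL);
  std::vector<double> buf(window * window);
  std::vector<char> bmask(window * window);
  double out[5];
  for (int r = half; r + half < nr; r += stride) {
    for (int c = half; c + half < nc; c += stride) {
      for (int wc = 0; wc < window; ++wc)
        for (int wr = 0; wr < window; ++wr) {
          int i = wc * window + wr;
          buf[i] = vals(r - half + wr, c - half + wc);
          bmask[i] = mask(r - half + wr, c - half + wc) ? 1 : 0;
        }
      metrics_core(buf.data(), bmask.data(), window, window, connectivity, out);
      np(r, c) = out[0]; lpi(r, c) = out[1]; ai(r, c) = out[2];
      division(r, c) = out[3]; shdi(r, c) = out[4];
    }
  }
  return List::create(_["np"] = np, _["lpi"] = lpi, _["ai"] = ai,
                      _["division"] = division, _["shdi"] = shdi);
}

// Mean of a numeric surface over the same windows as moving_window_cpp.
// [[Rcpp::export]]
NumericMatrix window_mean_cpp(NumericMatrix vals, LogicalMatrix mask,
                              int window, int stride) {
  int nr = vals.nrow(), nc = vals.ncol();
  int half = window / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int r = half; r + half < nr; r += stride) {
    for (int c = half; c + half < nc; c += stride) {
      double s = 0.0, n = 0.0;
      for (int wc = c - half; wc <= c + half; ++wc)
        for (int wr = r - half; wr <= r + half; ++wr)
          if (mask(wr, wc)) { s += vals(wr, wc); n += 1.0; }
      if (n > 0) out(r, c) = s / n;
    }
  }
  return out;
}
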