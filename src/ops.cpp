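#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disk-neighborhood offsets for a given radius (dr*dr + dc*dc <= r*r).
static std::vector<std::pair<int,int> > disk_offsets(int radius) {
  std::vector<std::pair<int,int> > off;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

static double median_of(std::vector<double>& v) {
  size_t n = v.size();
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
  return 0.5 * (hi + v[mid - 1]);
}

// Rank (median) filter over a disk neighborhood clipped to the image bounds.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(const NumericMatrix& img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(off.size());
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        int r = i + off[k].first, c = j + off[k].second;
        if (r >= 0 && r < nr && c >= 0 && c < nc) buf.push_back(img(r, c));
      }
      out(i, j) = median_of(buf);
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Separable convolution with a centered odd-length kernel, replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(const NumericMatrix& img, const NumericVector& kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kl = kernel.size(), half = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int r = i + k - half;
        if (r < 0) r = 0; else if (r >= nr) r = nr - 1;
        s += kernel[k] * img(r, j);
      }
      tmp(i, j) = s;
    }
  // along cols (horizontal direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int k = 0; k < kl; ++k) {
        int c = j + k - half;
        if (c < 0) c = 0; else if (c >= nc) c = nc - 1;
        s += kernel[k] * tmp(i, c);
      }
      out(i, j) = s;
    }
  return out;
}

struct DSU {
  std::vector<int> parent;
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
};

// Candidate local minima with topographic prominence (persistence by
// watershed-by-flooding on pixel order ascending in value, 8-connectivity).
// Returns one row per candidate minimum: row, col (1-based), value, prominence.
// The surviving global minimum gets prominence max(img) - min.
// [[Rcpp::export]]
DataFrame cpp_minima_prominence(const NumericMatrix& img) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double* v = img.begin();
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] < v[b];
    int ra = a % nr, ca = a / nr, rb = b % nr, cb = b / nr;
    if (ra != rb) return ra < rb;
    return ca < cb;
  });
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[order[i]] = i;

  DSU dsu; dsu.parent.resize(n);
  std::vector<int> comp_min(n, -1);      // root -> index of component minimum
  std::vector<char> seen(n, 0);
  std::vector<int> min_idx; std::vector<double> min_val, prom;

  for (int oi = 0; oi < n; ++oi) {
    int p = order[oi];
    int pi = p % nr, pj = p / nr;
    dsu.parent[p] = p;
    seen[p] = 1;
    int root = -1;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int qi = pi + di, qj = pj + dj;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int q = qi + qj * nr;
        if (!seen[q]) continue;
        int rq = dsu.find(q);
        if (root == -1) {
          dsu.parent[p] = rq;
          comp_min[rq] = comp_min[rq]; // unchanged; p is not lower
          root = rq;
        } else if (rq != root) {
          // merge: component with the higher minimum dies at this saddle level
          int ra = root, rb = rq;
          int ma = comp_min[ra], mb = comp_min[rb];
          // survivor = lower minimum; ties by processing order (rank)
          bool a_survives = (v[ma] < v[mb]) || (v[ma] == v[mb] && rank[ma] < rank[mb]);
          int die = a_survives ? mb : ma;
          int surv = a_survives ? ra : rb;
          int dead = a_survives ? rb : ra;
          min_idx.push_back(die);
          min_val.push_back(v[die]);
          prom.push_back(v[p] - v[die]);
          dsu.parent[dead] = surv;
          dsu.parent[p] = surv;
          root = surv;
        }
      }
    }
    if (root == -1) comp_min[p] = p;  // new local minimum seeds a component
  }
  // remaining components: prominence relative to the global maximum
  double vmax = *std::max_element(v, v + n);
  std::vector<char> emitted(n, 0);
  for (size_t k = 0; k < min_idx.size(); ++k) emitted[min_idx[k]] = 1;
  for (int i = 0; i < n; ++i) {
    if (comp_min[i] == i && dsu.find(i) == i && !emitted[i]) {
      min_idx.push_back(i);
      min_val.push_back(v[i]);
      prom.push_back(vmax - v[i]);
    }
  }
  int m = min_idx.size();
  IntegerVector rrow(m), rcol(m); NumericVector rval(m), rprom(m);
  for (int k = 0; k < m; ++k) {
    rrow[k] = min_idx[k] % nr + 1;
    rcol[k] = min_idx[k] / nr + 1;
    rval[k] = min_val[k];
    rprom[k] = prom[k];
  }
  return DataFrame::create(_["row"] = rrow, _["col"] = rcol,
                           _["value"] = rval, _["prominence"] = rprom);
}
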