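// Connected-component labelling, cluster masses and the TFCE transform on
// an arbitrary adjacency graph (CSR: 0-based offsets/indices), plus batch
// versions that scan a matrix of permutation statistic maps.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Label connected components of {i : v[i] > thr}. Labels start at 1;
// inactive nodes get 0.
static int label_components(const double* v, int n, double thr,
                            const int* off, const int* idx, int* lab,
                            std::vector<int>& stack) {
  std::fill(lab, lab + n, 0);
  int ncl = 0;
  for (int s = 0; s < n; ++s) {
    if (v[s] <= thr || lab[s] != 0) continue;
    ++ncl;
    stack.clear();
    stack.push_back(s);
    lab[s] = ncl;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int e = off[u]; e < off[u + 1]; ++e) {
        int w = idx[e];
        if (v[w] > thr && lab[w] == 0) {
          lab[w] = ncl;
          stack.push_back(w);
        }
      }
    }
  }
  return ncl;
}

// [[Rcpp::export]]
IntegerVector cpp_components(NumericVector v, double thr, IntegerVector off,
                             IntegerVector idx) {
  int n = v.size();
  IntegerVector lab(n);
  std::vector<int> stack;
  label_components(v.begin(), n, thr, off.begin(), idx.begin(), lab.begin(),
                   stack);
  return lab;
}

// Max over connected clusters of |sum of v| for positive (v > thr) and,
// when two_sided, negative (v < -thr) excursions. 0 when none.
static double max_cluster_mass(const double* v, int n, double thr,
                               const int* off, const int* idx, bool two_sided,
                               std::vector<int>& lab, std::vector<int>& stack,
                               std::vector<double>& neg) {
  double best = 0.0;
  lab.assign(n, 0);
  int ncl = label_components(v, n, thr, off, idx, lab.data(), stack);
  if (ncl > 0) {
    std::vector<double> mass(ncl, 0.0);
    for (int i = 0; i < n; ++i)
      if (lab[i] > 0) mass[lab[i] - 1] += v[i];
    for (int c = 0; c < ncl; ++c) best = std::max(best, std::fabs(mass[c]));
  }
  if (two_sided) {
    neg.resize(n);
    for (int i = 0; i < n; ++i) neg[i] = -v[i];
    ncl = label_components(neg.data(), n, thr, off, idx, lab.data(), stack);
    if (ncl > 0) {
      std::vector<double> mass(ncl, 0.0);
      for (int i = 0; i < n; ++i)
        if (lab[i] > 0) mass[lab[i] - 1] += neg[i];
      for (int c = 0; c < ncl; ++c) best = std::max(best, std::fabs(mass[c]));
    }
  }
  return best;
}

// [[Rcpp::export]]
double cpp_max_cluster_mass(NumericVector v, double thr, IntegerVector off,
                            IntegerVector idx, bool two_sided) {
  std::vector<int> lab, stack;
  std::vector<double> neg;
  return max_cluster_mass(v.begin(), v.size(), thr, off.begin(), idx.begin(),
                          two_sided, lab, stack, neg);
}

// stats: n_nodes x n_perm matrix; returns max cluster mass per column.
// [[Rcpp::export]]
NumericVector cpp_perm_max_mass(NumericMatrix stats, double thr,
                                IntegerVector off, IntegerVector idx,
                                bool two_sided) {
  int n = stats.nrow(), P = stats.ncol();
  NumericVector out(P);
  std::vector<int> lab, stack;
  std::vector<double> neg;
  for (int p = 0; p < P; ++p) {
    out[p] = max_cluster_mass(&stats(0, p), n, thr, off.begin(), idx.begin(),
                              two_sided, lab, stack, neg);
  }
  return out;
}

// --- TFCE ------------------------------------------------------------------

struct DSU {
  std::vector<int> parent, size;
  void init(int n) {
    parent.resize(n);
    size.assign(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int u) {
    while (parent[u] != u) {
      parent[u] = parent[parent[u]];
      u = parent[u];
    }
    return u;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Accumulate sign * extent^E * h^H * dh over descending thresholds for the
// positive part of v (caller negates v for the negative part). Incremental
// union-find: the active set only grows as h decreases.
static void tfce_accum(const std::vector<double>& v, int n, const int* off,
                       const int* idx, double E, double H, double dh,
                       int nsteps, double sign, double* out, DSU& dsu,
                       std::vector<int>& ord, std::vector<char>& active,
                       std::vector<int>& actlist) {
  double vmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (v[i] > vmax) vmax = v[i];
  if (vmax <= 0.0) return;
  double step = dh > 0.0 ? dh : vmax / nsteps;
  int jmax = (int)std::floor(vmax / step + 1e-12);
  if (jmax < 1) jmax = 1;
  ord.clear();
  for (int i = 0; i < n; ++i)
    if (v[i] > 0.0) ord.push_back(i);
  std::sort(ord.begin(), ord.end(),
            [&v](int a, int b) { return v[a] > v[b]; });
  dsu.init(n);
  std::fill(active.begin(), active.end(), 0);
  actlist.clear();
  size_t ptr = 0;
  for (int j = jmax; j >= 1; --j) {
    double h = j * step;
    while (ptr < ord.size() && v[ord[ptr]] >= h) {
      int u = ord[ptr++];
      active[u] = 1;
      dsu.size[u] = 1;
      actlist.push_back(u);
      for (int e = off[u]; e < off[u + 1]; ++e) {
        int w = idx[e];
        if (active[w]) dsu.unite(u, w);
      }
    }
    double hh = sign * std::pow(h, H) * step;
    for (size_t q = 0; q < actlist.size(); ++q) {
      int u = actlist[q];
      out[u] += std::pow((double)dsu.size[dsu.find(u)], E) * hh;
    }
  }
}

// Signed TFCE transform; dh <= 0 means max|v|/nsteps.
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector v, IntegerVector off, IntegerVector idx,
                       double E, double H, int nsteps, double dh) {
  int n = v.size();
  NumericVector out(n);
  double amax = 0.0;
  for (int i = 0; i < n; ++i) amax = std::max(amax, std::fabs(v[i]));
  if (amax == 0.0) return out;
  double step = dh > 0.0 ? dh : amax / nsteps;
  std::vector<double> pos(n), neg(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = v[i] > 0.0 ? v[i] : 0.0;
    neg[i] = v[i] < 0.0 ? -v[i] : 0.0;
  }
  DSU dsu;
  std::vector<int> ord, actlist;
  std::vector<char> active(n, 0);
  tfce_accum(pos, n, off.begin(), idx.begin(), E, H, step, nsteps, 1.0,
             out.begin(), dsu, ord, active, actlist);
  tfce_accum(neg, n, off.begin(), idx.begin(), E, H, step, nsteps, -1.0,
             out.begin(), dsu, ord, active, actlist);
  return out;
}

// Max |TFCE| per column of a permutation statistic matrix; each column uses
// its own dh = max|v|/nsteps.
// [[Rcpp::export]]
NumericVector cpp_perm_max_tfce(NumericMatrix stats, IntegerVector off,
                                IntegerVector idx, double E, double H,
                                int nsteps) {
  int n = stats.nrow(), P = stats.ncol();
  NumericVector out(P);
  DSU dsu;
  std::vector<int> ord, actlist;
  std::vector<char> active(n, 0);
  std::vector<double> pos(n), neg(n), buf(n);
  for (int p = 0; p < P; ++p) {
    const double* v = &stats(0, p);
    double amax = 0.0;
    for (int i = 0; i < n; ++i) amax = std::max(amax, std::fabs(v[i]));
    if (amax == 0.0) {
      out[p] = 0.0;
      continue;
    }
    double step = amax / nsteps;
    for (int i = 0; i < n; ++i) {
      pos[i] = v[i] > 0.0 ? v[i] : 0.0;
      neg[i] = v[i] < 0.0 ? -v[i] : 0.0;
      buf[i] = 0.0;
    }
    tfce_accum(pos, n, off.begin(), idx.begin(), E, H, step, nsteps, 1.0,
               buf.data(), dsu, ord, active, actlist);
    tfce_accum(neg, n, off.begin(), idx.begin(), E, H, step, nsteps, -1.0,
               buf.data(), dsu, ord, active, actlist);
    double best = 0.0;
    for (int i = 0; i < n; ++i) best = std::max(best, std::fabs(buf[i]));
    out[p] = best;
  }
  return out;
}
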