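#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving + union by size.
static inline int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// TFCE enhancement of a non-negative statistic map on an arbitrary adjacency
// graph (CSR: nbr_ptr has V+1 entries, nbr_idx 0-based neighbour lists).
// For each location x: TFCE(x) = sum over h = dh, 2dh, ..., <= t(x) of
// e(h, x)^E * h^H * dh, where e(h, x) is the size of the connected component
// of {t >= h} containing x. Thresholds are processed from high to low with an
// incremental union-find, so each map costs O(n_steps * V_active).
static void tfce_core(const double* stat, int V,
                      const int* nbr_ptr, const int* nbr_idx,
                      double E, double H, int n_steps, double dh,
                      double* out) {
  double mx = 0.0;
  for (int i = 0; i < V; ++i) {
    out[i] = 0.0;
    if (stat[i] > mx) mx = stat[i];
  }
  if (mx <= 0.0) return;
  if (dh <= 0.0) dh = mx / n_steps;

  std::vector<int> order(V);
  for (int i = 0; i < V; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(V), csize(V, 0);
  std::vector<char> active(V, 0);
  for (int i = 0; i < V; ++i) parent[i] = i;

  int pos = 0;            // pointer into the sorted order
  std::vector<int> act;   // activated voxels so far
  act.reserve(V);
  int top = (int)std::floor(mx / dh + 1e-12);
  if (top > n_steps) top = n_steps;
  for (int j = top; j >= 1; --j) {
    double h = j * dh;
    while (pos < V && stat[order[pos]] >= h) {
      int v = order[pos++];
      active[v] = 1;
      csize[v] = 1;
      act.push_back(v);
      for (int q = nbr_ptr[v]; q < nbr_ptr[v + 1]; ++q) {
        int u = nbr_idx[q];
        if (!active[u]) continue;
        int ra = uf_find(parent, v), rb = uf_find(parent, u);
        if (ra != rb) {
          if (csize[ra] < csize[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          csize[ra] += csize[rb];
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (size_t a = 0; a < act.size(); ++a) {
      int v = act[a];
      int r = uf_find(parent, v);
      out[v] += std::pow((double)csize[r], E) * hH;
    }
  }
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector nbr_ptr,
                       IntegerVector nbr_idx, double E, double H,
                       int n_steps, double dh) {
  int V = stat.size();
  NumericVector out(V);
  if (n_steps < 1) stop("n_steps must be positive");
  tfce_core(REAL(stat), V, INTEGER(nbr_ptr), INTEGER(nbr_idx), E, H,
            n_steps, dh, REAL(out));
  return out;
}

// Permutation null of the maximum TFCE statistic for a mass-univariate simple
// regression with per-block intercepts. Yc is the sessions x V block-centered
// response; xc the block-centered predictor. Each column of `perms` holds
// 0-based row indices (a permutation within blocks). For each permutation the
// per-location slope t statistic is computed in closed form and TFCE applied
// to its positive and negated parts; the map-wide maxima are recorded.
// [[Rcpp::export(name = ".perm_tfce_null_cpp")]]
List perm_tfce_null_cpp(NumericMatrix Yc, NumericVector xc,
                        IntegerMatrix perms, IntegerVector nbr_ptr,
                        IntegerVector nbr_idx, double E, double H,
                        int n_steps, int df) {
  int n = Yc.nrow(), V = Yc.ncol(), P = perms.ncol();
  double sxx = 0.0;
  for (int i = 0; i < n; ++i) sxx += xc[i] * xc[i];
  if (sxx <= 0.0) stop("constant predictor");
  std::vector<double> yss(V, 0.0);
  for (int j = 0; j < V; ++j) {
    double s = 0.0;
    const double* col = &Yc(0, j);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    yss[j] = s;
  }
  NumericVector max_pos(P), max_neg(P);
  std::vector<double> t(V), part(V), enh(V), xp(n);
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) xp[i] = xc[perms(i, p)];
    for (int j = 0; j < V; ++j) {
      double cp = 0.0;
      const double* col = &Yc(0, j);
      for (int i = 0; i < n; ++i) cp += xp[i] * col[i];
      double rss = yss[j] - cp * cp / sxx;
      if (rss < 1e-300) rss = 1e-300;
      t[j] = (cp / std::sqrt(sxx)) / std::sqrt(rss / df);
    }
    double mp = 0.0, mn = 0.0;
    for (int j = 0; j < V; ++j) part[j] = t[j] > 0 ? t[j] : 0.0;
    tfce_core(part.data(), V, INTEGER(nbr_ptr), INTEGER(nbr_idx), E, H,
              n_steps, 0.0, enh.data());
    for (int j = 0; j < V; ++j) if (enh[j] > mp) mp = enh[j];
    for (int j = 0; j < V; ++j) part[j] = t[j] < 0 ? -t[j] : 0.0;
    tfce_core(part.data(), V, INTEGER(nbr_ptr), INTEGER(nbr_idx), E, H,
              n_steps, 0.0, enh.data());
    for (int j = 0; j < V; ++j) if (enh[j] > mn) mn = enh[j];
    max_pos[p] = mp;
    max_neg[p] = mn;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["max_pos"] = max_pos, _["max_neg"] = max_neg);
}
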