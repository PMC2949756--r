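// Hot loops for the ZOOPS EM engine: window scoring under a log-odds
// matrix, weighted M-step letter counts, and the Altschul-Erickson
// dinucleotide-preserving shuffle. Sequence codes are 1..4 (A,C,G,T) with
// NA for masked bases; windows touching NA score NA.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".scoreWindowsC")]]
NumericVector scoreWindowsC(IntegerVector codes, NumericMatrix lo) {
  const int w = lo.ncol();
  const int n = codes.size();
  const int nw = n - w + 1;
  NumericVector s(nw > 0 ? nw : 0);
  if (nw <= 0) return s;
  const int *x = INTEGER(codes);
  double *out = REAL(s);
  // local copy of the 4 x w score matrix, laid out [j][letter]
  std::vector<double> m(4 * w);
  for (int j = 0; j < w; ++j)
    for (int a = 0; a < 4; ++a) m[4 * j + a] = lo(a, j);
  // nextNA[i]: smallest index >= i holding NA (or n)
  std::vector<int> nextNA(n + 1);
  nextNA[n] = n;
  for (int i = n - 1; i >= 0; --i)
    nextNA[i] = (x[i] == NA_INTEGER) ? i : nextNA[i + 1];
  for (int g = 0; g < nw; ++g) {
    if (nextNA[g] < g + w) { out[g] = NA_REAL; continue; }
    double acc = 0.0;
    const int *xr = x + g;
    for (int j = 0; j < w; ++j) acc += m[4 * j + (xr[j] - 1)];
    out[g] = acc;
  }
  return s;
}

// Weighted letter counts for the M-step. vidx holds 1-based window start
// positions in `codes`; zF/zR are forward/minus-strand responsibilities
// (zR may be length 0 when only the forward strand is scanned). A
// minus-strand site contributes the complemented letter at the mirrored
// motif position.
// [[Rcpp::export(name = ".mstepCountsC")]]
NumericMatrix mstepCountsC(IntegerVector codes, IntegerVector vidx,
                           NumericVector zF, NumericVector zR, int w) {
  NumericMatrix counts(4, w);
  const bool rev = zR.size() > 0;
  const int *x = INTEGER(codes);
  const int *vi = INTEGER(vidx);
  const double *zf = REAL(zF);
  const double *zr = rev ? REAL(zR) : (double *)0;
  double *cn = REAL(counts);
  const int nv = vidx.size();
  for (int i = 0; i < nv; ++i) {
    const int g = vi[i] - 1;
    const double f = zf[i];
    const int *xr = x + g;
    if (rev) {
      const double r = zr[i];
      for (int j = 0; j < w; ++j) {
        const int c = xr[j];             // valid windows contain no NA
        cn[4 * j + (c - 1)] += f;
        cn[4 * (w - 1 - j) + (4 - c)] += r;
      }
    } else {
      for (int j = 0; j < w; ++j) cn[4 * j + (xr[j] - 1)] += f;
    }
  }
  return counts;
}

static int randBelow(int n) {  // uniform in 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Altschul-Erickson dinucleotide shuffle of one code vector. Codes are
// 1..5 (5 = masked). Preserves exact dinucleotide counts, first and last
// letter. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export(name = ".eulerShuffleC")]]
IntegerVector eulerShuffleC(IntegerVector x) {
  const int n = x.size();
  IntegerVector out(clone(x));
  if (n < 3) return out;
  const int V = 5;
  std::vector<std::vector<int> > edges(V + 1);
  for (int i = 0; i + 1 < n; ++i) edges[x[i]].push_back(x[i + 1]);
  const int last = x[n - 1];
  std::vector<int> verts;
  for (int u = 1; u <= V; ++u)
    if (!edges[u].empty() || u == last) verts.push_back(u);
  if (verts.size() < 2) return out;

  std::vector<int> lastEdge(V + 1, 0);
  for (int tries = 0; tries < 10000; ++tries) {
    for (size_t vi = 0; vi < verts.size(); ++vi) {
      const int u = verts[vi];
      if (u == last || edges[u].empty()) { lastEdge[u] = 0; continue; }
      lastEdge[u] = edges[u][randBelow((int)edges[u].size())];
    }
    bool ok = true;
    for (size_t vi = 0; vi < verts.size() && ok; ++vi) {
      int u = verts[vi];
      if (u == last || edges[u].empty()) continue;
      int cur = u, steps = 0;
      while (cur != last) {
        cur = lastEdge[cur];
        if (cur == 0 || ++steps > V + 1) { ok = false; break; }
      }
    }
    if (ok) break;
  }

  std::vector<std::vector<int> > pool(V + 1);
  std::vector<size_t> ptr(V + 1, 0);
  for (size_t vi = 0; vi < verts.size(); ++vi) {
    const int u = verts[vi];
    pool[u] = edges[u];
    if (u != last && !pool[u].empty()) {
      // remove one instance of the reserved last edge
      for (size_t k = 0; k < pool[u].size(); ++k)
        if (pool[u][k] == lastEdge[u]) {
          pool[u].erase(pool[u].begin() + k);
          break;
        }
    }
    // Fisher-Yates
    for (int k = (int)pool[u].size() - 1; k > 0; --k) {
      int r = randBelow(k + 1);
      std::swap(pool[u][k], pool[u][r]);
    }
  }

  int cur = x[0];
  out[0] = cur;
  for (int i = 1; i < n; ++i) {
    int nxt;
    if (ptr[cur] < pool[cur].size()) nxt = pool[cur][ptr[cur]++];
    else nxt = lastEdge[cur];
    out[i] = nxt;
    cur = nxt;
  }
  return out;
}
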