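#include <Rcpp.h>
using namespace Rcpp;

// Component counts of the adjacency graph of two genomes given as partner
// vectors (1-based extremity codes, 0 = telomere).  Returns
// (cycles, odd_paths, even_paths); the DCJ distance is N - C - I/2.
// [[Rcpp::export]]
IntegerVector ag_counts_cpp(IntegerVector pa, IntegerVector pb) {
  const int m = pa.size();
  std::vector<char> vis(m, 0);
  int cycles = 0, odd = 0, even = 0;
  // paths start at a vertex missing an edge in one of the two genomes
  for (int s = 0; s < m; ++s) {
    if (vis[s] || (pa[s] != 0 && pb[s] != 0)) continue;
    int cur = s;
    int gph = (pa[s] == 0) ? 1 : 0;  // next edge to use: 0 = A, 1 = B
    int v = 0;
    for (;;) {
      vis[cur] = 1; ++v;
      int nxt = (gph == 0) ? pa[cur] : pb[cur];
      if (nxt == 0) break;
      cur = nxt - 1;
      gph = 1 - gph;
    }
    if (v % 2 == 1) ++odd; else ++even;
  }
  for (int s = 0; s < m; ++s) {
    if (vis[s]) continue;
    int cur = s, gph = 0;
    for (;;) {
      vis[cur] = 1;
      int nxt = (gph == 0) ? pa[cur] : pb[cur];
      cur = nxt - 1;
      gph = 1 - gph;
      if (cur == s) break;
    }
    ++cycles;
  }
  return IntegerVector::create(cycles, odd, even);
}

// Twice the completed score (2*C + I) of the graph between a *partial*
// median partner vector pm (-1 = undecided, 0 = telomere) and a fully
// decided leaf partner vector pl.  Only components closed by decided edges
// count; a path counts only if both its ends are genuine telomeres.
// [[Rcpp::export]]
int score2_cpp(IntegerVector pm, IntegerVector pl) {
  const int m = pm.size();
  std::vector<char> vis(m, 0);
  int score2 = 0;
  for (int s = 0; s < m; ++s) {
    if (vis[s] || (pm[s] > 0 && pl[s] != 0)) continue;
    // s is an endpoint: median edge absent/undecided, or leaf telomere
    bool start_ok, end_ok = false;
    int cur = s, gph;
    if (pm[s] <= 0) { start_ok = (pm[s] == 0); gph = 1; }
    else            { start_ok = true;          gph = 0; }  // leaf telomere
    int v = 0;
    for (;;) {
      vis[cur] = 1; ++v;
      int nxt;
      if (gph == 0) {
        nxt = pm[cur];
        if (nxt <= 0) { end_ok = (nxt == 0); break; }
      } else {
        nxt = pl[cur];
        if (nxt == 0) { end_ok = true; break; }
      }
      cur = nxt - 1;
      gph = 1 - gph;
    }
    // avoid double-handling: when both ends are endpoints the walk from the
    // first marks all vertices, so the second start is skipped via vis[]
    if (start_ok && end_ok && v % 2 == 1) score2 += 1;
    (void)0;
  }
  for (int s = 0; s < m; ++s) {
    if (vis[s]) continue;
    // remaining components are cycles of decided edges
    int cur = s, gph = 0;
    for (;;) {
      vis[cur] = 1;
      int nxt = (gph == 0) ? pm[cur] : pl[cur];
      cur = nxt - 1;
      gph = 1 - gph;
      if (cur == s) break;
    }
    score2 += 2;
  }
  return score2;
}
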