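#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths by Dijkstra's algorithm on a dense nonnegative
// length matrix (R_PosInf where no direct edge). O(n^2) per source, which is
// optimal for dense networks. The matrix must be symmetric (undirected
// graph); relaxation reads column u, which is contiguous in memory.
// [[Rcpp::export(name = ".dijkstraAll")]]
NumericMatrix dijkstraAll(NumericMatrix len) {
  const int n = len.nrow();
  NumericMatrix d(n, n);
  const double *L = REAL(len);
  std::vector<double> dist(n);
  std::vector<char> done(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v) {
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      }
      if (u < 0) break;  // remaining nodes unreachable
      done[u] = 1;
      const double *col = L + (std::size_t)u * n;  // lengths to/from u
      const double du = dist[u];
      for (int v = 0; v < n; ++v) {
        if (done[v]) continue;
        const double w = col[v];
        if (w < R_PosInf && du + w < dist[v]) dist[v] = du + w;
      }
    }
    for (int v = 0; v < n; ++v) d(s, v) = dist[v];
  }
  return d;
}
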