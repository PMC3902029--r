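#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Graphs arrive as CSR adjacency: offsets (n+1, 0-based) and targets
// (2m, 0-based). Built once in R per graph; every traversal here is O(n + m).

// [[Rcpp::export]]
IntegerVector cpp_bfs_distances(IntegerVector offsets, IntegerVector targets,
                                IntegerVector sources) {
  int n = offsets.size() - 1;
  IntegerVector dist(n, -1);
  std::vector<int> queue;
  queue.reserve(n);
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    if (s < 0 || s >= n) stop("BFS source index out of range");
    if (dist[s] < 0) {
      dist[s] = 0;
      queue.push_back(s);
    }
  }
  for (std::size_t h = 0; h < queue.size(); ++h) {
    int v = queue[h];
    int dv = dist[v];
    for (int e = offsets[v]; e < offsets[v + 1]; ++e) {
      int u = targets[e];
      if (dist[u] < 0) {
        dist[u] = dv + 1;
        queue.push_back(u);
      }
    }
  }
  return dist;
}

// Exact eccentricity of every node by one BFS per source.
// Requires a connected graph; stops if any BFS fails to reach all nodes.
// [[Rcpp::export]]
IntegerVector cpp_all_eccentricities(IntegerVector offsets, IntegerVector targets) {
  int n = offsets.size() - 1;
  IntegerVector ecc(n, 0);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    queue[tail++] = s;
    int far = 0;
    while (head < tail) {
      int v = queue[head++];
      int dv = dist[v];
      if (dv > far) far = dv;
      for (int e = offsets[v]; e < offsets[v + 1]; ++e) {
        int u = targets[e];
        if (dist[u] < 0) {
          dist[u] = dv + 1;
          queue[tail++] = u;
        }
      }
    }
    if (tail < n)
      stop("graph is disconnected: eccentricities are defined on a connected graph; extract the giant component first");
    ecc[s] = far;
  }
  return ecc;
}

// Connected-component membership labels (0-based, in discovery order of the
// lowest-index unvisited node).
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector offsets, IntegerVector targets) {
  int n = offsets.size() - 1;
  IntegerVector comp(n, -1);
  std::vector<int> queue(n);
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    int head = 0, tail = 0;
    comp[s] = label;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (int e = offsets[v]; e < offsets[v + 1]; ++e) {
        int u = targets[e];
        if (comp[u] < 0) {
          comp[u] = label;
          queue[tail++] = u;
        }
      }
    }
    ++label;
  }
  return comp;
}

static inline int rmat_quadrant(double a, double b, double c) {
  double u = unif_rand();
  if (u < a) return 0;
  if (u < a + b) return 1;
  if (u < a + b + c) return 2;
  return 3;
}

// R-MAT edge sampler: each candidate edge descends `levels` quadrant choices
// of the 2^levels x 2^levels adjacency matrix; self-loops and duplicate
// undirected pairs are resampled so exactly m_target distinct edges result.
// Uses R's RNG, so set.seed() on the R side makes draws reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_rmat_edges(int levels, int m_target, double a, double b,
                             double c, double d, int max_attempts) {
  if (levels < 1 || levels > 30) stop("levels must be between 1 and 30");
  std::unordered_set<uint64_t> seen;
  seen.reserve(static_cast<std::size_t>(m_target) * 2);
  IntegerMatrix out(m_target, 2);
  int found = 0;
  long attempts = 0;
  while (found < m_target) {
    if (++attempts > max_attempts) {
      stop("R-MAT sampler exhausted max_attempts (%d) with %d of %d distinct edges realised",
           max_attempts, found, m_target);
    }
    uint64_t row = 0, col = 0;
    for (int l = 0; l < levels; ++l) {
      int q = rmat_quadrant(a, b, c);
      row = (row << 1) | (q >> 1);
      col = (col << 1) | (q & 1);
    }
    if (row == col) continue;
    uint64_t lo = row < col ? row : col;
    uint64_t hi = row < col ? col : row;
    uint64_t key = (lo << 32) | hi;
    if (!seen.insert(key).second) continue;
    out(found, 0) = static_cast<int>(lo);
    out(found, 1) = static_cast<int>(hi);
    ++found;
  }
  return out;
}

// Tally of quadrant choices over n independent recursion steps; exposes the
// sampler used by cpp_rmat_edges for distributional checks.
// [[Rcpp::export]]
IntegerVector cpp_rmat_quadrant_counts(int n, double a, double b, double c) {
  IntegerVector counts(4, 0);
  for (int i = 0; i < n; ++i) counts[rmat_quadrant(a, b, c)]++;
  return counts;
}
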