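#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance, self-matches
// excluded, N - m templates for both orders as in the canonical definition).
//
// Box-assisted counting: templates are hashed by their first two embedding
// coordinates on a grid of cell size u. Two m-length templates within
// Chebyshev distance u necessarily fall in the same or adjacent cells of
// that grid, so only pairs from neighbouring cells are compared in full.
// This keeps the cost near the number of actual matches even for strongly
// autocorrelated (smooth) signals, where a one-dimensional window would
// admit nearly all pairs.
//
// Returns c(B, A): B = m-length matches, A = (m+1)-length matches, each
// counted once per unordered pair.

static inline int64_t cell_key(int cx, int cy) {
  return (static_cast<int64_t>(cx) << 32) ^ (static_cast<uint32_t>(cy));
}

// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double u) {
  const int N = x.size();
  const int n = N - m;  // number of templates
  if (n < 2) stop("sequence too short for embedding dimension m");
  if (m < 1) stop("embedding dimension m must be >= 1");

  double B = 0.0, A = 0.0;

  if (u <= 0.0) {
    // degenerate tolerance: only exact ties match; fall back to the plain
    // pairwise scan (rare in practice)
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        bool ok = true;
        for (int k = 0; k < m; ++k) {
          if (x[i + k] != x[j + k]) { ok = false; break; }
        }
        if (!ok) continue;
        B += 1.0;
        if (x[i + m] == x[j + m]) A += 1.0;
      }
    }
    return NumericVector::create(B, A);
  }

  // grid on the first two coordinates (first coordinate twice when m = 1)
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(2 * n);
  const int c2 = (m >= 2) ? 1 : 0;  // second boxing coordinate offset
  for (int i = 0; i < n; ++i) {
    const int cx = static_cast<int>(std::floor(x[i] / u));
    const int cy = static_cast<int>(std::floor(x[i + c2] / u));
    grid[cell_key(cx, cy)].push_back(i);
  }

  // neighbour offsets covering each unordered cell pair once
  static const int half[4][2] = {{1, -1}, {1, 0}, {1, 1}, {0, 1}};

  for (const auto& kv : grid) {
    const std::vector<int>& pts = kv.second;
    const int cx = static_cast<int>(kv.first >> 32);
    const int cy = static_cast<int>(static_cast<uint32_t>(kv.first));
    // pairs within the cell
    for (size_t a = 0; a < pts.size(); ++a) {
      for (size_t b = a + 1; b < pts.size(); ++b) {
        const int i = pts[a], j = pts[b];
        bool ok = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > u) { ok = false; break; }
        }
        if (!ok) continue;
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= u) A += 1.0;
      }
    }
    // pairs against half of the neighbouring cells
    for (int h = 0; h < 4; ++h) {
      auto it = grid.find(cell_key(cx + half[h][0], cy + half[h][1]));
      if (it == grid.end()) continue;
      const std::vector<int>& other = it->second;
      for (int i : pts) {
        for (int j : other) {
          bool ok = true;
          for (int k = 0; k < m; ++k) {
            if (std::fabs(x[i + k] - x[j + k]) > u) { ok = false; break; }
          }
          if (!ok) continue;
          B += 1.0;
          if (std::fabs(x[i + m] - x[j + m]) <= u) A += 1.0;
        }
      }
    }
  }
  return NumericVector::create(B, A);
}
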