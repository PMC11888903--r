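#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Vietoris-Rips persistence by boundary-matrix reduction over F2 in the
// "twist" column order (higher simplex dimensions first, clearing the column
// of every simplex paired as a birth). Scales are radius units: a simplex
// enters the filtration at half its largest pairwise vertex distance, so two
// points join when d <= 2*eps. Filtration ties are broken by
// (scale, dimension, lexicographic vertex tuple), which fixes the pairing.

namespace {

struct Simplex {
  double scale;
  int dim;
  int a, b, c; // vertex ids, ascending; unused = -1
};

inline bool simplexLess(const Simplex &x, const Simplex &y) {
  if (x.scale != y.scale) return x.scale < y.scale;
  if (x.dim != y.dim) return x.dim < y.dim;
  if (x.a != y.a) return x.a < y.a;
  if (x.b != y.b) return x.b < y.b;
  return x.c < y.c;
}

// symmetric difference of two ascending index vectors
inline void symDiff(std::vector<int> &dst, const std::vector<int> &src,
                    std::vector<int> &tmp) {
  tmp.clear();
  std::set_symmetric_difference(dst.begin(), dst.end(), src.begin(), src.end(),
                                std::back_inserter(tmp));
  dst.swap(tmp);
}

} // namespace

// [[Rcpp::export(name = ".vrReduceCpp")]]
NumericMatrix vrReduceCpp(NumericMatrix dist, double maxScale, int maxDim) {
  const int n = dist.nrow();
  if (maxDim < 0 || maxDim > 1)
    stop("maxDim must be 0 or 1");

  std::vector<Simplex> simplices;
  simplices.reserve(static_cast<size_t>(n) * (n + 1) / 2);

  for (int i = 0; i < n; ++i) simplices.push_back({0.0, 0, i, -1, -1});

  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.5 * dist(i, j);
      if (s <= maxScale) simplices.push_back({s, 1, i, j, -1});
    }

  if (maxDim >= 1) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double sij = 0.5 * dist(i, j);
        if (sij > maxScale) continue;
        for (int k = j + 1; k < n; ++k) {
          double s = std::max(sij, 0.5 * std::max(dist(i, k), dist(j, k)));
          if (s <= maxScale) simplices.push_back({s, 2, i, j, k});
        }
      }
  }

  std::sort(simplices.begin(), simplices.end(), simplexLess);
  const int S = static_cast<int>(simplices.size());

  // facet position lookup
  std::vector<int> vertexPos(n, -1);
  std::unordered_map<int64_t, int> edgePos;
  edgePos.reserve(static_cast<size_t>(S));
  for (int s = 0; s < S; ++s) {
    const Simplex &sx = simplices[s];
    if (sx.dim == 0) vertexPos[sx.a] = s;
    else if (sx.dim == 1)
      edgePos[static_cast<int64_t>(sx.a) * n + sx.b] = s;
  }

  std::vector<std::vector<int>> cols(S);
  for (int s = 0; s < S; ++s) {
    const Simplex &sx = simplices[s];
    if (sx.dim == 1) {
      cols[s] = {vertexPos[sx.a], vertexPos[sx.b]};
    } else if (sx.dim == 2) {
      cols[s] = {edgePos[static_cast<int64_t>(sx.a) * n + sx.b],
                 edgePos[static_cast<int64_t>(sx.a) * n + sx.c],
                 edgePos[static_cast<int64_t>(sx.b) * n + sx.c]};
    }
    std::sort(cols[s].begin(), cols[s].end());
  }

  std::vector<int> ownerOfLow(S, -1);   // birth index -> death column index
  std::vector<char> pairedBirth(S, 0), pairedDeath(S, 0), cleared(S, 0);
  std::vector<int> tmp;

  const int topDim = (maxDim >= 1) ? 2 : 1;
  for (int d = topDim; d >= 1; --d) {
    for (int j = 0; j < S; ++j) {
      if (simplices[j].dim != d || cleared[j]) continue;
      std::vector<int> &col = cols[j];
      while (!col.empty()) {
        int low = col.back();
        int owner = ownerOfLow[low];
        if (owner < 0) break;
        symDiff(col, cols[owner], tmp);
      }
      if (!col.empty()) {
        int low = col.back();
        ownerOfLow[low] = j;
        pairedBirth[low] = 1;
        pairedDeath[j] = 1;
        cols[low].clear();
        cleared[low] = 1;
      }
    }
  }

  std::vector<std::array<double, 4>> bars; // dim, birth, death, capped
  for (int i = 0; i < S; ++i) {
    if (pairedBirth[i]) {
      int j = ownerOfLow[i];
      int bd = simplices[i].dim;
      if (bd <= maxDim)
        bars.push_back({static_cast<double>(bd), simplices[i].scale,
                        simplices[j].scale, 0.0});
    } else if (!pairedDeath[i]) {
      // zero (or cleared) column never used as a pivot: essential class
      int bd = simplices[i].dim;
      if (bd <= maxDim)
        bars.push_back({static_cast<double>(bd), simplices[i].scale, maxScale,
                        1.0});
    }
  }

  NumericMatrix out(static_cast<int>(bars.size()), 4);
  for (size_t r = 0; r < bars.size(); ++r)
    for (int c = 0; c < 4; ++c) out(static_cast<int>(r), c) = bars[r][c];
  colnames(out) = CharacterVector::create("dim", "birth", "death", "capped");
  return out;
}
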