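#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Level-synchronous immersion watershed restricted to a region mask.
//
// Pixels are processed by ascending gradient level. Within a level, the
// unassigned level set is flooded from the already-labeled catchment basins
// by synchronous breadth-first waves (geodesic influence zones): a wave
// pixel inherits the unique basin label seen among previously assigned
// neighbors; pixels reached by two or more distinct basins at the same wave
// become watershed-line pixels (-1), as do pixels reachable only through
// line pixels. Level-set pixels not reached by any basin are regional
// minima and seed new basins. 8-connectivity throughout. The wave-at-a-time
// update makes the result independent of pixel enumeration order.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(const NumericMatrix& grad, const LogicalMatrix& region) {
  const int H = grad.nrow(), W = grad.ncol();
  IntegerMatrix lab(H, W); // 0 = unassigned/outside, -1 = line, k>=1 = basin
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  std::vector<int> px; // linear indices (col-major) of region pixels
  px.reserve(H * (size_t)W / 4 + 1);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (region(r, c)) px.push_back(c * H + r);
  if (px.empty()) return lab;

  std::stable_sort(px.begin(), px.end(), [&](int a, int b) {
    return grad[a] < grad[b];
  });

  std::vector<signed char> state(H * (size_t)W, 0); // per level: 1 in-S, 2 visited
  int nextBasin = 0;
  size_t i = 0;
  while (i < px.size()) {
    size_t j = i;
    double h = grad[px[i]];
    while (j < px.size() && grad[px[j]] == h) ++j;

    // S = this level's pixels
    for (size_t t = i; t < j; ++t) state[px[t]] = 1;

    // seed wave: S-pixels adjacent to an assigned pixel
    std::vector<int> wave;
    for (size_t t = i; t < j; ++t) {
      int p = px[t], r = p % H, c = p / H;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (lab(rr, cc) != 0) { wave.push_back(p); break; }
      }
    }
    for (size_t t = 0; t < wave.size(); ++t) state[wave[t]] = 2;

    while (!wave.empty()) {
      // label the whole wave from pre-wave assignments only
      std::vector<int> wlab(wave.size());
      for (size_t t = 0; t < wave.size(); ++t) {
        int p = wave[t], r = p % H, c = p / H;
        int found = 0; // unique basin label, -2 if conflicting
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int l = lab(rr, cc);
          if (l > 0) {
            if (found == 0) found = l;
            else if (found != l) { found = -2; break; }
          }
        }
        wlab[t] = (found > 0) ? found : -1;
      }
      std::vector<int> next;
      for (size_t t = 0; t < wave.size(); ++t) lab[wave[t]] = wlab[t];
      for (size_t t = 0; t < wave.size(); ++t) {
        int p = wave[t], r = p % H, c = p / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int q = cc * H + rr;
          if (state[q] == 1) { state[q] = 2; next.push_back(q); }
        }
      }
      wave.swap(next);
    }

    // unreached level pixels: new minima, one basin per connected component
    for (size_t t = i; t < j; ++t) {
      int p0 = px[t];
      if (state[p0] != 1) continue;
      ++nextBasin;
      std::vector<int> stack(1, p0);
      state[p0] = 2;
      lab[p0] = nextBasin;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % H, c = p / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int q = cc * H + rr;
          if (state[q] == 1) {
            state[q] = 2;
            lab[q] = nextBasin;
            stack.push_back(q);
          }
        }
      }
    }

    for (size_t t = i; t < j; ++t) state[px[t]] = 0;
    i = j;
  }
  return lab;
}
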