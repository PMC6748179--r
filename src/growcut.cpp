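#include <Rcpp.h>
using namespace Rcpp;

// Synchronous GrowCut iterations on a scalar-feature image graph with Moore
// connectivity. Labels: 0 = none, 1 = background, 2 = foreground. All nodes
// read generation t and write generation t+1. A node is conquered by the
// neighbour with the largest attack strength theta_f * g(c_e, c_f) strictly
// exceeding its own strength; ties are broken by the fixed neighbour scan
// order N, NE, E, SE, S, SW, W, NW (earlier wins). h counts label changes.
// [[Rcpp::export]]
List growcut_iterate_cpp(NumericMatrix feat, IntegerMatrix label0,
                         NumericMatrix strength0, IntegerMatrix h0,
                         double max_pairwise, int max_iters) {
  const int H = feat.nrow(), W = feat.ncol();
  IntegerMatrix lab = clone(label0), lab_next(H, W);
  NumericMatrix str = clone(strength0), str_next(H, W);
  IntegerMatrix h = clone(h0);

  // scan order N, NE, E, SE, S, SW, W, NW as (dy, dx)
  const int dy[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dx[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  int iters = 0;
  bool converged = false;

  for (int it = 0; it < max_iters; ++it) {
    bool changed = false;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        double best_s = str(y, x);
        int best_l = lab(y, x);
        bool conquered = false;
        for (int k = 0; k < 8; ++k) {
          const int ny = y + dy[k], nx = x + dx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (lab(ny, nx) == 0) continue;  // unlabelled nodes never attack
          double g = 1.0;
          if (max_pairwise > 0.0) {
            g = 1.0 - std::abs(feat(y, x) - feat(ny, nx)) / max_pairwise;
            if (g < 0.0) g = 0.0;
            if (g > 1.0) g = 1.0;
          }
          const double atk = str(ny, nx) * g;
          if (atk > best_s) {
            best_s = atk;
            best_l = lab(ny, nx);
            conquered = true;
          }
        }
        lab_next(y, x) = best_l;
        str_next(y, x) = best_s;
        if (conquered) {
          changed = true;
          if (best_l != lab(y, x)) h(y, x) += 1;
        }
      }
    }
    iters = it + 1;
    for (int i = 0; i < H * W; ++i) {
      lab[i] = lab_next[i];
      str[i] = str_next[i];
    }
    if (!changed) {
      converged = true;
      break;
    }
  }

  return List::create(_["label"] = lab, _["strength"] = str, _["changes"] = h,
                      _["iterations"] = iters, _["converged"] = converged);
}
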