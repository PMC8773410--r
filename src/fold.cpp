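#include <Rcpp.h>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand over nested structures.
//
// Energy model: a structure is a set of nested base pairs (Watson-Crick or
// G:U) with hairpin loops of at least `min_loop` unpaired bases. Its energy
// is the sum of stacking terms over adjacent pairs (i,j)/(i+1,j-1) plus one
// helix-initiation penalty per maximal helix. Since all stacking terms are
// negative and the initiation penalty positive, lone pairs never pay off and
// the empty structure bounds the MFE at 0.
//
// V(i,j): best energy with (i,j) paired, the initiation of the helix that
//         contains (i,j) accounted at its innermost pair.
// W(i,j): best energy of any structure on i..j.

static const double INF = 1e18;

// base encoding: A=0, C=1, G=2, U/T=3
// pair types (1-based into the 6x6 stack table): AU UA GC CG GU UG
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stacks,
                  double helix_init, int min_loop) {
  const int n = seq.size();
  IntegerVector pairs(n, -1);
  if (n < min_loop + 2) {
    return List::create(_["mfe"] = 0.0, _["pairs"] = pairs);
  }

  std::vector<double> V((size_t)n * n, INF), W((size_t)n * n, 0.0);
  auto at = [n](int i, int j) { return (size_t)i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_type(seq[i], seq[j]);
      if (pt > 0) {
        double v = helix_init + W[at(i + 1, j - 1)];
        int pti = pair_type(seq[i + 1], seq[j - 1]);
        if (pti > 0 && j - 1 - (i + 1) > min_loop &&
            V[at(i + 1, j - 1)] < INF / 2) {
          double vs = stacks(pt - 1, pti - 1) + V[at(i + 1, j - 1)];
          if (vs < v) v = vs;
        }
        V[at(i, j)] = v;
      }
      double w = (pt > 0) ? V[at(i, j)] : INF;
      for (int k = i; k < j; ++k) {
        double cand = W[at(i, k)] + ((k + 1 <= j - 1) ? W[at(k + 1, j)] : 0.0);
        // note W[at(k+1, j)] with k+1 == j is W(j,j) = 0 already
        if (k + 1 == j) cand = W[at(i, k)];
        else cand = W[at(i, k)] + W[at(k + 1, j)];
        if (cand < w) w = cand;
      }
      W[at(i, j)] = w;
    }
  }

  // traceback
  const double eps = 1e-9;
  std::vector<std::pair<std::pair<int, int>, bool>> stack; // ((i,j), inV)
  stack.push_back({{0, n - 1}, false});
  while (!stack.empty()) {
    auto item = stack.back();
    stack.pop_back();
    int i = item.first.first, j = item.first.second;
    bool inV = item.second;
    if (j - i <= min_loop) continue;
    if (inV) {
      pairs[i] = j;
      pairs[j] = i;
      int pt = pair_type(seq[i], seq[j]);
      int pti = pair_type(seq[i + 1], seq[j - 1]);
      if (pti > 0 && j - 1 - (i + 1) > min_loop &&
          V[at(i + 1, j - 1)] < INF / 2 &&
          std::abs(V[at(i, j)] -
                   (stacks(pt - 1, pti - 1) + V[at(i + 1, j - 1)])) < eps) {
        stack.push_back({{i + 1, j - 1}, true});
      } else {
        stack.push_back({{i + 1, j - 1}, false});
      }
    } else {
      double w = W[at(i, j)];
      int pt = pair_type(seq[i], seq[j]);
      if (pt > 0 && V[at(i, j)] < INF / 2 &&
          std::abs(w - V[at(i, j)]) < eps) {
        stack.push_back({{i, j}, true});
        continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        double cand = (k + 1 == j) ? W[at(i, k)]
                                   : W[at(i, k)] + W[at(k + 1, j)];
        if (std::abs(w - cand) < eps) {
          stack.push_back({{i, k}, false});
          if (k + 1 < j) stack.push_back({{k + 1, j}, false});
          done = true;
        }
      }
      if (!done) stop("folding traceback failed (internal error)");
    }
  }

  double mfe = W[at(0, n - 1)];
  if (mfe > 0) mfe = 0.0; // empty structure
  return List::create(_["mfe"] = mfe, _["pairs"] = pairs);
}
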