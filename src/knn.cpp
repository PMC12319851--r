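#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Brute-force k-nearest-neighbour majority vote in Euclidean feature space.
// Deterministic: neighbour ties at equal distance keep training order, and
// vote ties go to the lowest label value. Points are copied into contiguous
// row-major buffers so the hot loop streams through memory.
// [[Rcpp::export(name = ".knn_label_cpp")]]
IntegerVector knn_label_cpp(NumericMatrix query, NumericMatrix train,
                            IntegerVector labels, int k) {
  const int q = query.nrow(), m = train.nrow(), d = query.ncol();
  if (train.ncol() != d) stop("dimension mismatch between query and train");
  if (labels.size() != m) stop("labels length must match train rows");
  if (k < 1 || k > m) stop("k must be in 1..nrow(train)");

  int maxlab = 0;
  for (int i = 0; i < m; ++i) if (labels[i] > maxlab) maxlab = labels[i];

  // row-major copies
  std::vector<double> tr((size_t)m * d), qu((size_t)q * d);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < d; ++c) tr[(size_t)j * d + c] = train(j, c);
  for (int i = 0; i < q; ++i)
    for (int c = 0; c < d; ++c) qu[(size_t)i * d + c] = query(i, c);
  const int *lab = INTEGER(labels);

  IntegerVector out(q);
  std::vector<double> bestd(k);
  std::vector<int> bestl(k);
  std::vector<int> votes(maxlab + 1);

  for (int i = 0; i < q; ++i) {
    const double *qp = &qu[(size_t)i * d];
    int filled = 0;
    double worst = R_PosInf;
    int worst_at = 0;
    const double *tp = &tr[0];
    for (int j = 0; j < m; ++j, tp += d) {
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = qp[c] - tp[c];
        dist += diff * diff;
      }
      if (filled < k) {
        bestd[filled] = dist; bestl[filled] = lab[j];
        ++filled;
        if (filled == k) {
          worst_at = (int)(std::max_element(bestd.begin(), bestd.end()) -
                           bestd.begin());
          worst = bestd[worst_at];
        }
      } else if (dist < worst) {
        bestd[worst_at] = dist; bestl[worst_at] = lab[j];
        worst_at = (int)(std::max_element(bestd.begin(), bestd.end()) -
                         bestd.begin());
        worst = bestd[worst_at];
      }
    }
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < filled; ++t) ++votes[bestl[t]];
    int win = 0, winv = -1;
    for (int l = 0; l <= maxlab; ++l)
      if (votes[l] > winv) { winv = votes[l]; win = l; }  // lowest label wins ties
    out[i] = win;
  }
  return out;
}
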