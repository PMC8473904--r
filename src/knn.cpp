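#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mean test accuracy of deterministic majority-vote KNN over several k.
//
// D: nTest x nTrain squared-distance matrix.
// trainLab/testLab: 1-based class indices.
// ks: neighbourhood sizes (each clamped to nTrain).
// Neighbour order ties are broken by training-sample index; vote ties by the
// lowest class index, so the result is fully deterministic.
// [[Rcpp::export]]
double knn_mean_accuracy_cpp(NumericMatrix D, IntegerVector trainLab,
                             IntegerVector testLab, IntegerVector ks,
                             int nClass) {
  const int nTest = D.nrow(), nTrain = D.ncol(), nK = ks.size();
  std::vector<int> correct(nK, 0);
  std::vector<int> ord(nTrain);
  std::vector<int> votes(nClass);

  for (int i = 0; i < nTest; ++i) {
    for (int j = 0; j < nTrain; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double da = D(i, a), db = D(i, b);
      if (da != db) return da < db;
      return a < b;
    });
    // incremental vote counting shared across the (sorted) k values
    std::fill(votes.begin(), votes.end(), 0);
    int taken = 0, ki = 0;
    for (int j = 0; j < nTrain && ki < nK; ++j) {
      votes[trainLab[ord[j]] - 1] += 1;
      ++taken;
      while (ki < nK && std::min<int>(ks[ki], nTrain) == taken) {
        int best = 0;
        for (int c = 1; c < nClass; ++c)
          if (votes[c] > votes[best]) best = c; // ties -> lowest class index
        if (best + 1 == testLab[i]) correct[ki] += 1;
        ++ki;
      }
    }
  }
  double acc = 0.0;
  for (int ki = 0; ki < nK; ++ki)
    acc += static_cast<double>(correct[ki]) / nTest;
  return acc / nK;
}
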