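// Deterministic k-nearest-neighbour prediction: Euclidean distance,
// majority vote; neighbour ties broken by lowest training index (stable
// sort on squared distance), vote ties by lowest class code. Determinism is
// required because the wrapper's fitness must be a pure function of the
// candidate subset within a run.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".knnPredictCpp")]]
IntegerVector knnPredictCpp(NumericMatrix train, IntegerVector trainY,
                            NumericMatrix test, int k, int nClasses) {
    const int nTr = train.nrow(), nTe = test.nrow(), d = train.ncol();
    if (k > nTr) stop("k exceeds the number of training samples");
    IntegerVector pred(nTe);
    std::vector<int> idx(nTr);
    std::vector<double> d2(nTr);
    std::vector<int> votes(nClasses);
    for (int t = 0; t < nTe; ++t) {
        for (int i = 0; i < nTr; ++i) {
            double s = 0.0;
            for (int j = 0; j < d; ++j) {
                const double diff = train(i, j) - test(t, j);
                s += diff * diff;
            }
            d2[i] = s;
            idx[i] = i;
        }
        std::stable_sort(idx.begin(), idx.end(),
                         [&](int a, int b) { return d2[a] < d2[b]; });
        std::fill(votes.begin(), votes.end(), 0);
        for (int j = 0; j < k; ++j) votes[trainY[idx[j]]] += 1;
        int best = 0;
        for (int c = 1; c < nClasses; ++c)
            if (votes[c] > votes[best]) best = c;
        pred[t] = best;
    }
    return pred;
}
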