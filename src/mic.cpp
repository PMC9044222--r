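// Characteristic-matrix estimator for the maximal information coefficient.
//
// For a pivot axis cut into q bins and budget B, the other axis is optimised
// exactly by dynamic programming over clump boundaries (an optimal partition
// never cuts inside a run of points that share a pivot bin, and tied values
// are never split). The pivot partition is a single mass equipartition for
// q >= 3; for q = 2 every candidate cut (value boundaries, capped at
// clumpFactor * 2 via mass equipartition) is enumerated, which makes all
// grids with min(i, j) = 2 exact. Both orientations are computed and merged
// entrywise. All logs are natural here; normalisation happens in R where the
// base cancels.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double xlogx(double p) {
    return p > 0.0 ? p * std::log(p) : 0.0;
}

// Greedy mass equipartition of ordered tie-groups into at most q bins.
static std::vector<int> equipartitionGroups(const std::vector<int> &counts,
                                            int q) {
    const int G = static_cast<int>(counts.size());
    long n = 0;
    for (int c : counts) n += c;
    std::vector<int> bin(G);
    double desired = static_cast<double>(n) / q;
    long before = 0, size = 0;
    int cur = 0;
    for (int g = 0; g < G; ++g) {
        const int c = counts[g];
        if (size != 0 && cur < q - 1 &&
            std::fabs(size + c - desired) >=
                std::fabs(static_cast<double>(size) - desired)) {
            ++cur;
            size = 0;
            desired = static_cast<double>(n - before) / (q - cur);
        }
        bin[g] = cur;
        size += c;
        before += c;
    }
    return bin;
}

struct Clump {
    std::vector<long> rows;  // per-row counts
    long total;
};

// Merge points (in x order, grouped by tied x) into clumps given the row of
// each point; consecutive pure clumps in the same row merge.
static std::vector<Clump> buildClumps(const std::vector<int> &xg,
                                      const std::vector<int> &rowOfPoint,
                                      int q) {
    std::vector<Clump> clumps;
    const int n = static_cast<int>(xg.size());
    int pos = 0;
    while (pos < n) {
        int end = pos;
        while (end < n && xg[end] == xg[pos]) ++end;
        Clump c;
        c.rows.assign(q, 0L);
        c.total = end - pos;
        int pure = rowOfPoint[pos];
        for (int t = pos; t < end; ++t) {
            c.rows[rowOfPoint[t]] += 1L;
            if (rowOfPoint[t] != pure) pure = -1;
        }
        if (!clumps.empty() && pure >= 0) {
            Clump &last = clumps.back();
            if (last.total == last.rows[pure]) {  // last is pure in same row
                last.rows[pure] += c.total;
                last.total += c.total;
                pos = end;
                continue;
            }
        }
        clumps.push_back(std::move(c));
        pos = end;
    }
    return clumps;
}

static std::vector<Clump> superClumps(const std::vector<Clump> &clumps,
                                      int cap) {
    if (static_cast<int>(clumps.size()) <= cap) return clumps;
    std::vector<int> sizes(clumps.size());
    for (size_t i = 0; i < clumps.size(); ++i)
        sizes[i] = static_cast<int>(clumps[i].total);
    std::vector<int> bin = equipartitionGroups(sizes, cap);
    std::vector<Clump> out;
    for (size_t i = 0; i < clumps.size(); ++i) {
        if (out.empty() || bin[i] != bin[i - 1]) {
            out.push_back(clumps[i]);
        } else {
            Clump &last = out.back();
            for (size_t r = 0; r < last.rows.size(); ++r)
                last.rows[r] += clumps[i].rows[r];
            last.total += clumps[i].total;
        }
    }
    return out;
}

// DP over clumps: for each column count l in 2..maxL, the maximal mutual
// information (nats) of an l-column partition against the fixed row
// assignment. Writes running results into half(l, q) as a max.
static void optimiseAxis(const std::vector<Clump> &clumps, int q, int maxL,
                         long n, NumericMatrix &half) {
    const int k = static_cast<int>(clumps.size());
    if (k < 2) return;
    // cumulative counts
    std::vector<long> cumTot(k + 1, 0L);
    std::vector<std::vector<long>> cum(k + 1, std::vector<long>(q, 0L));
    for (int t = 1; t <= k; ++t) {
        cumTot[t] = cumTot[t - 1] + clumps[t - 1].total;
        for (int r = 0; r < q; ++r)
            cum[t][r] = cum[t - 1][r] + clumps[t - 1].rows[r];
    }
    double HQ = 0.0;
    for (int r = 0; r < q; ++r)
        HQ -= xlogx(static_cast<double>(cum[k][r]) / n);

    // g(s, t): column over clumps s+1..t
    auto g = [&](int s, int t) {
        const double c = static_cast<double>(cumTot[t] - cumTot[s]);
        double val = -xlogx(c / n);
        for (int r = 0; r < q; ++r)
            val += xlogx(static_cast<double>(cum[t][r] - cum[s][r]) / n);
        return val;
    };

    const int L = std::min(maxL, k);
    std::vector<double> prev(k + 1, -1e300), curr(k + 1, -1e300);
    for (int t = 1; t <= k; ++t) prev[t] = g(0, t);
    for (int l = 2; l <= L; ++l) {
        std::fill(curr.begin(), curr.end(), -1e300);
        for (int t = l; t <= k; ++t) {
            double best = -1e300;
            for (int s = l - 1; s < t; ++s) {
                const double v = prev[s] + g(s, t);
                if (v > best) best = v;
            }
            curr[t] = best;
        }
        const double I = curr[k] + HQ;
        if (I > half(l, q)) half(l, q) = I;
        std::swap(prev, curr);
    }
}

// Tie-group ids in sorted order for one variable; also per-point group id in
// the original point order.
static void groupIds(const NumericVector &v, std::vector<int> &idOfPoint,
                     std::vector<int> &groupCounts) {
    const int n = v.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    idOfPoint.assign(n, 0);
    groupCounts.clear();
    int gid = -1;
    double last = 0.0;
    for (int k = 0; k < n; ++k) {
        if (gid < 0 || v[ord[k]] != last) {
            ++gid;
            groupCounts.push_back(0);
            last = v[ord[k]];
        }
        idOfPoint[ord[k]] = gid;
        groupCounts[gid] += 1;
    }
}

// One orientation: pivot = b (rows), optimised axis = a (columns).
// Fills half(l, q) = max MI (nats) for l columns on a, q rows on b.
static void computeHalf(const NumericVector &a, const NumericVector &b,
                        int B, int clumpFactor, NumericMatrix &half) {
    const int n = a.size();
    std::vector<int> agOfPoint, aCounts, bgOfPoint, bCounts;
    groupIds(a, agOfPoint, aCounts);
    groupIds(b, bgOfPoint, bCounts);
    const int Gb = static_cast<int>(bCounts.size());
    if (static_cast<int>(aCounts.size()) < 2 || Gb < 2) return;

    // points in a-sorted order
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int i, int j) { return a[i] < a[j]; });
    std::vector<int> xg(n), ybg(n);
    for (int k = 0; k < n; ++k) {
        xg[k] = agOfPoint[ord[k]];
        ybg[k] = bgOfPoint[ord[k]];
    }

    const int maxQ = B / 2;
    for (int q = 2; q <= maxQ && q <= Gb; ++q) {
        const int maxL = B / q;
        const int cap = clumpFactor * maxL;
        std::vector<std::vector<int>> rowMaps;  // bGroup -> row id
        if (q == 2) {
            // candidate single cuts between b-groups, capped at
            // clumpFactor * 2 by mass equipartition of the groups
            std::vector<int> cuts;
            const int capCuts = clumpFactor * 2;
            if (Gb - 1 <= capCuts) {
                for (int c = 1; c < Gb; ++c) cuts.push_back(c);
            } else {
                std::vector<int> bin = equipartitionGroups(bCounts,
                                                           capCuts + 1);
                for (int g = 1; g < Gb; ++g)
                    if (bin[g] != bin[g - 1]) cuts.push_back(g);
            }
            for (int c : cuts) {
                std::vector<int> rm(Gb, 0);
                for (int g = c; g < Gb; ++g) rm[g] = 1;
                rowMaps.push_back(std::move(rm));
            }
        } else {
            rowMaps.push_back(equipartitionGroups(bCounts, q));
        }
        std::vector<int> rowOfPoint(n);
        for (const std::vector<int> &rm : rowMaps) {
            int usedRows = 0;
            for (int g = 0; g < Gb; ++g) usedRows = std::max(usedRows, rm[g]);
            ++usedRows;
            for (int k = 0; k < n; ++k) rowOfPoint[k] = rm[ybg[k]];
            std::vector<Clump> clumps =
                superClumps(buildClumps(xg, rowOfPoint, usedRows), cap);
            // pad row dimension to q for indexing consistency
            optimiseAxis(clumps, usedRows, maxL, n, half);
        }
        Rcpp::checkUserInterrupt();
    }
}

// [[Rcpp::export(name = ".micRawCpp")]]
NumericMatrix micRawCpp(NumericVector x, NumericVector y, int B,
                        int clumpFactor) {
    const int maxD = B / 2;
    // half matrices indexed (l, q), 0..maxD rows/cols; row 0/1 unused
    NumericMatrix hx(maxD + 1, maxD + 1);  // columns on x, rows on y
    NumericMatrix hy(maxD + 1, maxD + 1);  // columns on y, rows on x
    computeHalf(x, y, B, clumpFactor, hx);
    computeHalf(y, x, B, clumpFactor, hy);
    // raw(i, j): best MI (nats) for a grid with i columns (x) and j rows (y)
    NumericMatrix raw(maxD - 1, maxD - 1);
    for (int i = 2; i <= maxD; ++i)
        for (int j = 2; j <= maxD; ++j) {
            if (static_cast<long>(i) * j > B) {
                raw(i - 2, j - 2) = NA_REAL;
                continue;
            }
            raw(i - 2, j - 2) = std::max(hx(i, j), hy(j, i));
        }
    // a grid may leave cells empty, so entries are monotone in (i, j):
    // propagate the running maximum over the admissible region
    for (int i = 2; i <= maxD; ++i)
        for (int j = 2; j <= maxD; ++j) {
            if (static_cast<long>(i) * j > B) continue;
            double v = raw(i - 2, j - 2);
            if (i > 2) v = std::max(v, raw(i - 3, j - 2));
            if (j > 2) v = std::max(v, raw(i - 2, j - 3));
            raw(i - 2, j - 2) = v;
        }
    return raw;
}
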