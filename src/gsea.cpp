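#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment score.
//
// `w` holds the (already exponentiated, non-negative) weights of every gene
// in ranked order; `pos` holds the 1-based ranked positions of the set
// members, sorted ascending. The running sum increases by w[p]/NR at each
// member ("hit") and decreases by 1/(N - m) at each non-member ("miss").
// Between hits the path is linear, so its extrema occur immediately before
// or at a hit position; the path ends at exactly 0. The ES is the signed
// extreme deviation; on an exact tie of magnitudes the positive extreme is
// taken (deterministic).
static void es_core(const double* w, const int* pos, int m, int N,
                    double& es, int& at) {
    double NR = 0.0;
    for (int k = 0; k < m; ++k) NR += w[pos[k] - 1];
    const double nmiss = static_cast<double>(N - m);
    double cum = 0.0, maxdev = 0.0, mindev = 0.0;
    int maxat = 0, minat = 0;
    const bool flat = (NR <= 0.0); // all member weights zero: fall back to
                                   // the unweighted (classic) increments
    for (int k = 0; k < m; ++k) {
        const int p = pos[k];
        // just before the k-th hit: k hits and (p - 1 - k) misses passed
        double before = (flat ? (double)k / m : cum / NR)
            - (p - 1 - k) / nmiss;
        cum += w[p - 1];
        double after = (flat ? (double)(k + 1) / m : cum / NR)
            - (p - 1 - k) / nmiss;
        if (before < mindev) { mindev = before; minat = p - 1; }
        if (after  > maxdev) { maxdev = after;  maxat = p; }
    }
    // magnitude ties resolve to the positive extreme; the epsilon absorbs
    // float drift between the hit- and miss-side accumulations
    double big = std::max(std::max(maxdev, -mindev), 1.0);
    if (maxdev >= -mindev - 1e-9 * big) { es = maxdev; at = maxat; }
    else                                { es = mindev; at = minat; }
}

//' @noRd
// [[Rcpp::export(name = ".cppEnrichmentScore")]]
NumericVector cppEnrichmentScore(NumericVector w, IntegerVector positions) {
    const int N = w.size(), m = positions.size();
    if (m < 1 || m >= N)
        stop("set must have at least one member and one non-member in the list");
    std::vector<int> pos(positions.begin(), positions.end());
    std::sort(pos.begin(), pos.end());
    if (pos.front() < 1 || pos.back() > N)
        stop("member positions out of range");
    double es; int at;
    es_core(REAL(w), pos.data(), m, N, es, at);
    return NumericVector::create(_["es"] = es, _["position"] = (double)at);
}

// Partial Fisher-Yates draw of m distinct positions from 1..N using R's RNG
// (deterministic under set.seed). `idx` is a reusable 0..N-1 identity buffer;
// the swaps are undone in reverse order after the draw, keeping each call
// O(m) instead of O(N).
static void sample_positions(std::vector<int>& idx, int N, int m,
                             std::vector<int>& out, std::vector<int>& js) {
    for (int k = 0; k < m; ++k) {
        int j = k + (int)(unif_rand() * (N - k));
        if (j >= N) j = N - 1; // guard against unif_rand() == 1.0
        js[k] = j;
        std::swap(idx[k], idx[j]);
        out[k] = idx[k] + 1;
    }
    for (int k = m - 1; k >= 0; --k) std::swap(idx[k], idx[js[k]]);
}

//' @noRd
// [[Rcpp::export(name = ".cppPermutationES")]]
NumericVector cppPermutationES(NumericVector w, int m, int nPerm) {
    const int N = w.size();
    if (m < 1 || m >= N) stop("invalid set size for permutation null");
    if (nPerm < 1) stop("nPerm must be >= 1");
    NumericVector out(nPerm);
    std::vector<int> idx(N), pos(m), js(m);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int b = 0; b < nPerm; ++b) {
        sample_positions(idx, N, m, pos, js);
        std::sort(pos.begin(), pos.end());
        double es; int at;
        es_core(REAL(w), pos.data(), m, N, es, at);
        out[b] = es;
    }
    return out;
}
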