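#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// 64-bit finalizer (splitmix64); uniform over the full 64-bit range.
static inline uint64_t mix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Scan a sequence and report every k-mer whose canonical-strand hash falls
// below `threshold` (both in units of the 53-bit hash range kept exact in
// doubles). Offsets are 0-based positions of the k-mer's leftmost base on the
// forward strand; strand is 0 when the forward k-mer is the canonical
// representative, 1 when the reverse complement is. k-mers containing a
// non-ACGT base are never reported.
// [[Rcpp::export]]
List cpp_sketch(const std::string& seq, int k, double seed, double threshold) {
    const size_t n = seq.size();
    std::vector<int> offs;
    std::vector<double> hashes;
    std::vector<int> strands;
    if (k < 1 || n < (size_t)k)
        return List::create(_["offset"] = IntegerVector(0),
                            _["hash"] = NumericVector(0),
                            _["strand"] = IntegerVector(0));
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    const int shift = 2 * (k - 1);
    const uint64_t useed = (uint64_t)(int64_t)seed;
    uint64_t f = 0, r = 0;
    int valid = 0;  // number of consecutive valid bases ending at i
    for (size_t i = 0; i < n; ++i) {
        int b = base_code(seq[i]);
        if (b < 0) { valid = 0; f = 0; r = 0; continue; }
        f = ((f << 2) | (uint64_t)b) & mask;
        r = (r >> 2) | ((uint64_t)(3 - b) << shift);
        if (++valid < k) continue;
        uint64_t canon = (f <= r) ? f : r;
        uint64_t h = mix64(canon ^ useed) >> 11;  // top 53 bits, exact in double
        double hd = (double)h;
        if (hd < threshold) {
            offs.push_back((int)(i - k + 1));
            hashes.push_back(hd);
            strands.push_back(f <= r ? 0 : 1);
        }
    }
    return List::create(_["offset"] = wrap(offs),
                        _["hash"] = wrap(hashes),
                        _["strand"] = wrap(strands));
}

// Minimum of x over windows [starts[i], starts[i]+k) (0-based starts).
// [[Rcpp::export]]
IntegerVector cpp_window_min(IntegerVector x, IntegerVector starts, int k) {
    int m = starts.size(), n = x.size();
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) {
        int s = starts[i], mn = NA_INTEGER;
        for (int j = s; j < s + k && j < n; ++j)
            if (mn == NA_INTEGER || x[j] < mn) mn = x[j];
        out[i] = mn;
    }
    return out;
}

// Banded colinear chaining over anchors sorted by (q_index, t_index).
// score(j) = max(bonus, max_i score(i) + bonus - gap(i, j)) over the band_h
// anchors preceding j with strictly increasing q_index and t_index;
// gap = min(gap_cap, gap_scale * |dq_off - dt_off|). Ties broken toward the
// smaller predecessor index; best endpoint ties toward the smaller index.
// Returns the chosen anchors (1-based indices into the input) and the score.
// [[Rcpp::export]]
List cpp_chain(IntegerVector qi, IntegerVector ti,
               IntegerVector qo, IntegerVector to,
               double bonus, double gap_scale, double gap_cap, int band_h) {
    int n = qi.size();
    if (n == 0)
        return List::create(_["score"] = 0.0, _["idx"] = IntegerVector(0));
    std::vector<double> score(n);
    std::vector<int> parent(n, -1);
    for (int j = 0; j < n; ++j) {
        score[j] = bonus;
        int lo = j - band_h; if (lo < 0) lo = 0;
        for (int i = lo; i < j; ++i) {
            if (qi[i] >= qi[j] || ti[i] >= ti[j]) continue;
            double drift = std::fabs((double)(qo[j] - qo[i]) - (double)(to[j] - to[i]));
            double gap = gap_scale * drift;
            if (gap > gap_cap) gap = gap_cap;
            double cand = score[i] + bonus - gap;
            if (cand > score[j]) { score[j] = cand; parent[j] = i; }
        }
    }
    int best = 0;
    for (int j = 1; j < n; ++j) if (score[j] > score[best]) best = j;
    std::vector<int> path;
    for (int v = best; v >= 0; v = parent[v]) path.push_back(v + 1);
    std::reverse(path.begin(), path.end());
    return List::create(_["score"] = score[best], _["idx"] = wrap(path));
}

// Expand a chain into minimizer-space alignment operations. Unmatched hits
// strictly between consecutive anchors are paired positionally: min(u, v)
// pairs become mismatches (or matches when the hashes agree), the surplus
// becomes insertions (query surplus) or deletions (target surplus).
// op codes: 0 match, 1 mismatch, 2 insertion, 3 deletion. Indices are 0-based
// positions in the hit lists; -1 marks the absent side of an indel.
// [[Rcpp::export]]
DataFrame cpp_expand(IntegerVector cqi, IntegerVector cti,
                     NumericVector qh, NumericVector th) {
    std::vector<int> op, oqi, oti;
    int nc = cqi.size();
    for (int a = 0; a < nc; ++a) {
        if (a > 0) {
            int qa = cqi[a - 1], qb = cqi[a], ta = cti[a - 1], tb = cti[a];
            int u = qb - qa - 1, v = tb - ta - 1;
            int p = std::min(u, v);
            for (int j = 0; j < p; ++j) {
                int qj = qa + 1 + j, tj = ta + 1 + j;
                op.push_back(qh[qj] == th[tj] ? 0 : 1);
                oqi.push_back(qj); oti.push_back(tj);
            }
            for (int j = p; j < u; ++j) {           // query surplus: insertions
                op.push_back(2); oqi.push_back(qa + 1 + j); oti.push_back(-1);
            }
            for (int j = p; j < v; ++j) {           // target surplus: deletions
                op.push_back(3); oqi.push_back(-1); oti.push_back(ta + 1 + j);
            }
        }
        op.push_back(0); oqi.push_back(cqi[a]); oti.push_back(cti[a]);
    }
    return DataFrame::create(_["op"] = wrap(op), _["qIndex"] = wrap(oqi),
                             _["tIndex"] = wrap(oti));
}

// Length of the longest common subsequence of two numeric sequences;
// used to align corrected vs. ground-truth hash lists for precision/recall.
// [[Rcpp::export]]
int cpp_lcs(NumericVector a, NumericVector b) {
    int n = a.size(), m = b.size();
    if (n == 0 || m == 0) return 0;
    std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
            else cur[j] = std::max(prev[j], cur[j - 1]);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}
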