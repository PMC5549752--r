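#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch with free terminal gaps (semi-global / "overlap" mode).
// Scoring: match +1, mismatch -1, gap column -1; terminal overhangs free.
// Identity = matched columns / internal alignment columns, where "internal"
// means the aligned region between the first and last aligned position of the
// shorter overhang (terminal gaps are excluded from both numerator and
// denominator).

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP = -1;

static void nw_core(const std::string& a, const std::string& b,
                    int& matches, int& columns) {
    const int n = (int)a.size();
    const int m = (int)b.size();
    // DP matrix with free leading gaps: first row/col = 0.
    std::vector<int> S((size_t)(n + 1) * (m + 1), 0);
    // traceback: 0 stop (boundary), 1 diag, 2 up (gap in b), 3 left (gap in a)
    std::vector<unsigned char> T((size_t)(n + 1) * (m + 1), 0);
    const int W = m + 1;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int sub = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? MATCH : MISMATCH;
            const int d = S[(size_t)(i - 1) * W + (j - 1)] + sub;
            const int u = S[(size_t)(i - 1) * W + j] + GAP;
            const int l = S[(size_t)i * W + (j - 1)] + GAP;
            int best = d; unsigned char t = 1;
            if (u > best) { best = u; t = 2; }
            if (l > best) { best = l; t = 3; }
            S[(size_t)i * W + j] = best;
            T[(size_t)i * W + j] = t;
        }
    }
    // best end point on the last row or last column (free trailing gaps);
    // scan is deterministic: last column top-down, then last row left-right.
    int bi = n, bj = m, bs = S[(size_t)n * W + m];
    for (int i = 1; i <= n; ++i)
        if (S[(size_t)i * W + m] > bs) { bs = S[(size_t)i * W + m]; bi = i; bj = m; }
    for (int j = 1; j <= m; ++j)
        if (S[(size_t)n * W + j] > bs) { bs = S[(size_t)n * W + j]; bi = n; bj = j; }
    matches = 0; columns = 0;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
        const unsigned char t = T[(size_t)i * W + j];
        ++columns;
        if (t == 1) {
            if (a[(size_t)i - 1] == b[(size_t)j - 1]) ++matches;
            --i; --j;
        } else if (t == 2) {
            --i;
        } else {
            --j;
        }
    }
}

// [[Rcpp::export(name = ".nwIdentity")]]
NumericVector nw_identity(std::string a, std::string b) {
    if (a.empty() || b.empty())
        stop("sequences must be non-empty");
    int matches = 0, columns = 0;
    nw_core(a, b, matches, columns);
    const double id = columns > 0 ? (double)matches / (double)columns : 0.0;
    return NumericVector::create(_["identity"] = id,
                                 _["matches"] = (double)matches,
                                 _["columns"] = (double)columns);
}

// [[Rcpp::export(name = ".nwIdentityBatch")]]
NumericVector nw_identity_batch(std::string query, CharacterVector refs) {
    const int k = refs.size();
    NumericVector out(k);
    for (int r = 0; r < k; ++r) {
        const std::string b = as<std::string>(refs[r]);
        if (query.empty() || b.empty()) stop("sequences must be non-empty");
        int matches = 0, columns = 0;
        nw_core(query, b, matches, columns);
        out[r] = columns > 0 ? (double)matches / (double)columns : 0.0;
    }
    return out;
}
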