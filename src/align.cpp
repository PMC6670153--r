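#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Linear-gap pairwise alignment dynamic programming.
//
// Two variants back the EST machinery:
//  - overlap: global alignment with free end gaps (leading/trailing gaps in
//    either sequence cost nothing), the natural model for fragments of one
//    transcript that overlap partially.
//  - local: Smith-Waterman, used to place a called consensus inside a
//    transcript set.
//
// Traceback tie-break is fixed at diagonal > up (gap in b) > left (gap in
// a), which makes output deterministic; the end cell of the overlap variant
// is chosen, among maxima over the last row and column, nearest to the
// bottom-right corner (fewest end gaps).

static inline double subst(char x, char y, double match, double mismatch) {
    return (x == y) ? match : mismatch;
}

// [[Rcpp::export(name = ".alignOverlapC")]]
List alignOverlapC(std::string a, std::string b, double match,
                   double mismatch, double gap) {
    const int m = (int)a.size(), n = (int)b.size();
    if (m == 0 || n == 0)
        stop("sequences must be non-empty");
    std::vector<double> H((size_t)(m + 1) * (n + 1));
    auto at = [&](int i, int j) -> double& {
        return H[(size_t)i * (n + 1) + j];
    };
    for (int i = 0; i <= m; ++i) at(i, 0) = 0.0;  // free leading gaps
    for (int j = 0; j <= n; ++j) at(0, j) = 0.0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            double d = at(i - 1, j - 1) + subst(a[i - 1], b[j - 1],
                                                match, mismatch);
            double u = at(i - 1, j) + gap;
            double l = at(i, j - 1) + gap;
            at(i, j) = std::max(d, std::max(u, l));
        }
    }
    // end cell: max over last row/column, preferring proximity to (m, n)
    int bi = m, bj = n;
    double best = at(m, n);
    for (int i = m; i >= 0; --i)
        if (at(i, n) > best) { best = at(i, n); bi = i; bj = n; }
    for (int j = n; j >= 0; --j)
        if (at(m, j) > best) { best = at(m, j); bi = m; bj = j; }
    std::string ga, gb;
    // trailing free gaps
    for (int i = m; i > bi; --i) { ga += a[i - 1]; gb += '-'; }
    for (int j = n; j > bj; --j) { ga += '-'; gb += b[j - 1]; }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    std::string ca, cb;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
        double d = at(i - 1, j - 1) + subst(a[i - 1], b[j - 1],
                                            match, mismatch);
        if (at(i, j) == d) {
            ca += a[i - 1]; cb += b[j - 1]; --i; --j;
        } else if (at(i, j) == at(i - 1, j) + gap) {
            ca += a[i - 1]; cb += '-'; --i;
        } else {
            ca += '-'; cb += b[j - 1]; --j;
        }
    }
    while (i > 0) { ca += a[i - 1]; cb += '-'; --i; }  // free leading gaps
    while (j > 0) { ca += '-'; cb += b[j - 1]; --j; }
    std::reverse(ca.begin(), ca.end());
    std::reverse(cb.begin(), cb.end());
    return List::create(_["score"] = best,
                        _["a"] = ca + ga,
                        _["b"] = cb + gb);
}

// [[Rcpp::export(name = ".alignLocalC")]]
List alignLocalC(std::string a, std::string b, double match,
                 double mismatch, double gap) {
    const int m = (int)a.size(), n = (int)b.size();
    if (m == 0 || n == 0)
        stop("sequences must be non-empty");
    std::vector<double> H((size_t)(m + 1) * (n + 1), 0.0);
    auto at = [&](int i, int j) -> double& {
        return H[(size_t)i * (n + 1) + j];
    };
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            double d = at(i - 1, j - 1) + subst(a[i - 1], b[j - 1],
                                                match, mismatch);
            double u = at(i - 1, j) + gap;
            double l = at(i, j - 1) + gap;
            double v = std::max(0.0, std::max(d, std::max(u, l)));
            at(i, j) = v;
            if (v > best) { best = v; bi = i; bj = j; }  // first max wins
        }
    }
    std::string ga, gb;
    int i = bi, j = bj;
    int nmatch = 0, ncols = 0;
    while (i > 0 && j > 0 && at(i, j) > 0.0) {
        double d = at(i - 1, j - 1) + subst(a[i - 1], b[j - 1],
                                            match, mismatch);
        if (at(i, j) == d) {
            ga += a[i - 1]; gb += b[j - 1];
            if (a[i - 1] == b[j - 1]) ++nmatch;
            ++ncols; --i; --j;
        } else if (at(i, j) == at(i - 1, j) + gap) {
            ga += a[i - 1]; gb += '-'; ++ncols; --i;
        } else {
            ga += '-'; gb += b[j - 1]; ++ncols; --j;
        }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    return List::create(_["score"] = best,
                        _["a"] = ga, _["b"] = gb,
                        _["a_start"] = i, _["a_end"] = bi,
                        _["b_start"] = j, _["b_end"] = bj,
                        _["n_match"] = nmatch, _["n_cols"] = ncols);
}
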