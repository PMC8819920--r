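#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost Levenshtein distance, O(min(m,n)) memory, shared work buffers.
// With bound >= 0, returns any value > bound early once the bound cannot be
// beaten (every entry of a DP row exceeds it).
static int lev_b(const std::string& a, const std::string& b, int bound,
                 std::vector<int>& prev, std::vector<int>& cur) {
    const std::string& s = (a.size() <= b.size()) ? a : b;
    const std::string& t = (a.size() <= b.size()) ? b : a;
    const size_t m = s.size(), n = t.size();
    if (bound >= 0 && (int)(n - m) > bound) return bound + 1;
    if (prev.size() < m + 1) { prev.resize(m + 1); cur.resize(m + 1); }
    for (size_t i = 0; i <= m; ++i) prev[i] = (int)i;
    for (size_t j = 1; j <= n; ++j) {
        cur[0] = (int)j;
        int rowMin = cur[0];
        for (size_t i = 1; i <= m; ++i) {
            int sub = prev[i - 1] + (s[i - 1] == t[j - 1] ? 0 : 1);
            int v = std::min(sub, std::min(prev[i] + 1, cur[i - 1] + 1));
            cur[i] = v;
            if (v < rowMin) rowMin = v;
        }
        if (bound >= 0 && rowMin > bound) return bound + 1;
        std::swap(prev, cur);
    }
    return prev[m];
}

static int lev(const std::string& a, const std::string& b) {
    std::vector<int> prev, cur;
    return lev_b(a, b, -1, prev, cur);
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        String sa = a[i % a.size()], sb = b[i % b.size()];
        if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
        out[i] = lev(std::string(sa.get_cstring()), std::string(sb.get_cstring()));
    }
    return out;
}

// Full distance matrix x (rows) vs y (cols).
// [[Rcpp::export]]
IntegerMatrix cpp_levenshtein_matrix(CharacterVector x, CharacterVector y) {
    R_xlen_t nx = x.size(), ny = y.size();
    std::vector<std::string> xs(nx), ys(ny);
    for (R_xlen_t i = 0; i < nx; ++i) xs[i] = as<std::string>(x[i]);
    for (R_xlen_t j = 0; j < ny; ++j) ys[j] = as<std::string>(y[j]);
    IntegerMatrix out(nx, ny);
    std::vector<int> prev, cur;
    for (R_xlen_t i = 0; i < nx; ++i)
        for (R_xlen_t j = 0; j < ny; ++j)
            out(i, j) = lev_b(xs[i], ys[j], -1, prev, cur);
    return out;
}

// For each observed string: distance to nearest (L1) and second-nearest (L2)
// whitelist entry, and the index (1-based) of the unique nearest entry.
// L2 is NA (treated as +Inf by the caller) when the whitelist has one entry.
// [[Rcpp::export]]
List cpp_nearest_two(CharacterVector observed, CharacterVector whitelist) {
    R_xlen_t n = observed.size(), w = whitelist.size();
    std::vector<std::string> wl(w);
    for (R_xlen_t j = 0; j < w; ++j) wl[j] = as<std::string>(whitelist[j]);
    IntegerVector L1(n), L2(n), idx(n);
    std::vector<int> prev, cur;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (observed[i] == NA_STRING) {
            L1[i] = NA_INTEGER; L2[i] = NA_INTEGER; idx[i] = NA_INTEGER;
            continue;
        }
        std::string obs = as<std::string>(observed[i]);
        int best = INT_MAX, second = INT_MAX, bi = -1;
        for (R_xlen_t j = 0; j < w; ++j) {
            // only distances below the current second-best can change the
            // (L1, L2, index) outcome, so bound the DP by it
            int bound = (second == INT_MAX) ? -1 : second;
            int d = lev_b(obs, wl[j], bound, prev, cur);
            if (d < best) { second = best; best = d; bi = (int)j; }
            else if (d < second) { second = d; }
        }
        L1[i] = best;
        L2[i] = (w > 1) ? second : NA_INTEGER;
        idx[i] = bi + 1;
    }
    return List::create(_["L1"] = L1, _["L2"] = L2, _["index"] = idx);
}
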