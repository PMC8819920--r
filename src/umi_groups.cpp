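#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static int lev_bounded(const std::string& a, const std::string& b, int k) {
    // full DP; strings here are UMI-sized so a band is not worth it
    const size_t m = a.size(), n = b.size();
    if ((int)std::max(m, n) - (int)std::min(m, n) > k) return k + 1;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (size_t i = 0; i <= m; ++i) prev[i] = (int)i;
    for (size_t j = 1; j <= n; ++j) {
        cur[0] = (int)j;
        for (size_t i = 1; i <= m; ++i) {
            int sub = prev[i - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[i] = std::min(sub, std::min(prev[i] + 1, cur[i - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

struct UF {
    std::vector<int> p;
    UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[std::max(a,b)] = std::min(a,b); }
};

// Single-linkage grouping of strings whose Levenshtein distance is
// <= max_edits.  NA entries are singletons.  Group ids are 1-based and
// assigned by first appearance, so the labelling is deterministic for a given
// input order while the partition itself is order-independent.
// [[Rcpp::export]]
IntegerVector cpp_umi_groups(CharacterVector umis, int max_edits) {
    R_xlen_t n = umis.size();
    // collapse to unique strings first: exact duplicates are the common case
    std::unordered_map<std::string, int> uniq;
    std::vector<int> umap(n, -1);
    std::vector<std::string> ustr;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (umis[i] == NA_STRING) continue;
        std::string s = as<std::string>(umis[i]);
        auto it = uniq.find(s);
        if (it == uniq.end()) {
            uniq.emplace(s, (int)ustr.size());
            umap[i] = (int)ustr.size();
            ustr.push_back(s);
        } else umap[i] = it->second;
    }
    int u = (int)ustr.size();
    UF uf(u);
    if (max_edits >= 1 && u > 1) {
        if (max_edits == 1) {
            // pigeonhole: two strings at distance <= 1 share either their
            // first floor(Lmin/2) or last floor(Lmin/2) characters exactly
            size_t lmin = ustr[0].size();
            for (auto& s : ustr) lmin = std::min(lmin, s.size());
            size_t h = lmin / 2;
            if (h == 0) {
                for (int i = 0; i < u; ++i)
                    for (int j = i + 1; j < u; ++j)
                        if (lev_bounded(ustr[i], ustr[j], 1) <= 1) uf.unite(i, j);
            } else {
                std::unordered_map<std::string, std::vector<int>> bucket;
                for (int i = 0; i < u; ++i) {
                    const std::string& s = ustr[i];
                    bucket["P" + s.substr(0, h)].push_back(i);
                    bucket["S" + s.substr(s.size() - h)].push_back(i);
                }
                for (auto& kv : bucket) {
                    std::vector<int>& v = kv.second;
                    for (size_t a = 0; a < v.size(); ++a)
                        for (size_t b = a + 1; b < v.size(); ++b)
                            if (uf.find(v[a]) != uf.find(v[b]) &&
                                lev_bounded(ustr[v[a]], ustr[v[b]], 1) <= 1)
                                uf.unite(v[a], v[b]);
                }
            }
        } else {
            for (int i = 0; i < u; ++i)
                for (int j = i + 1; j < u; ++j)
                    if (lev_bounded(ustr[i], ustr[j], max_edits) <= max_edits)
                        uf.unite(i, j);
        }
    }
    // assign group ids by first appearance
    IntegerVector out(n);
    std::unordered_map<int, int> gid;
    int next = 1;
    for (R_xlen_t i = 0; i < n; ++i) {
        int key;
        if (umap[i] < 0) key = -(int)(i + 1);     // NA: its own group
        else key = uf.find(umap[i]);
        auto it = gid.find(key);
        if (it == gid.end()) { gid.emplace(key, next); out[i] = next; ++next; }
        else out[i] = it->second;
    }
    return out;
}
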