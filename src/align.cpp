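#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Semi-global ("infix") search: the whole pattern aligned against a substring
// of the text at minimal unit-cost edit distance.  Returns, per text, the
// minimal distance and the 1-based end position of the best match (leftmost on
// ties); start is recovered so the caller knows the matched window.
// [[Rcpp::export]]
DataFrame cpp_infix_search(std::string pattern, CharacterVector texts) {
    const size_t m = pattern.size();
    R_xlen_t n = texts.size();
    IntegerVector dist(n), endpos(n), startpos(n);
    std::vector<int> prev(m + 1), cur(m + 1);
    // parallel DP tracking the start column of each cell's alignment
    std::vector<int> pstart(m + 1), cstart(m + 1);
    for (R_xlen_t t = 0; t < n; ++t) {
        std::string txt = as<std::string>(texts[t]);
        const size_t L = txt.size();
        int best = (int)m, bestEnd = 0, bestStart = 0;
        for (size_t i = 0; i <= m; ++i) { prev[i] = (int)i; pstart[i] = 0; }
        for (size_t j = 1; j <= L; ++j) {
            cur[0] = 0; cstart[0] = (int)j;  // free start in text
            for (size_t i = 1; i <= m; ++i) {
                int sub = prev[i - 1] + (pattern[i - 1] == txt[j - 1] ? 0 : 1);
                int del = prev[i] + 1;   // consume text base
                int ins = cur[i - 1] + 1; // consume pattern base
                int v = sub; int st = pstart[i - 1];
                if (del < v) { v = del; st = pstart[i]; }
                if (ins < v) { v = ins; st = cstart[i - 1]; }
                cur[i] = v; cstart[i] = st;
            }
            if (cur[m] < best) { best = cur[m]; bestEnd = (int)j; bestStart = cstart[m]; }
            std::swap(prev, cur);
            std::swap(pstart, cstart);
        }
        dist[t] = best; endpos[t] = bestEnd; startpos[t] = bestStart + 1;
        if (bestEnd == 0) { // pattern never consumed any text (empty text)
            startpos[t] = NA_INTEGER; endpos[t] = NA_INTEGER;
        }
    }
    return DataFrame::create(_["dist"] = dist, _["start"] = startpos,
                             _["end"] = endpos);
}

struct SWResult {
    double score;
    int q_start, q_end, r_start, r_end; // 1-based, inclusive
    int n_cols, n_match;
};

// Smith-Waterman with affine gaps (Gotoh), full traceback.
static SWResult sw_align(const std::string& q, const std::string& r,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
    const int m = (int)q.size(), n = (int)r.size();
    SWResult res{0.0, 0, 0, 0, 0, 0, 0};
    if (m == 0 || n == 0) return res;
    const double NEG = -1e30;
    std::vector<double> H((m + 1) * (n + 1), 0.0);
    std::vector<double> E((m + 1) * (n + 1), NEG); // gap in query (consume r)
    std::vector<double> F((m + 1) * (n + 1), NEG); // gap in ref (consume q)
    // traceback codes: 0 stop, 1 diag, 2 up(F), 3 left(E)
    std::vector<unsigned char> TB((m + 1) * (n + 1), 0);
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int k = i * (n + 1) + j;
            double e = std::max(H[k - 1] + gap_open + gap_extend,
                                E[k - 1] + gap_extend);
            double f = std::max(H[k - (n + 1)] + gap_open + gap_extend,
                                F[k - (n + 1)] + gap_extend);
            double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
            double d = H[k - (n + 2)] + s;
            double h = std::max(0.0, std::max(d, std::max(e, f)));
            E[k] = e; F[k] = f; H[k] = h;
            if (h == 0.0) TB[k] = 0;
            else if (h == d) TB[k] = 1;
            else if (h == f) TB[k] = 2;
            else TB[k] = 3;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0.0) return res;
    // traceback
    int i = bi, j = bj, ncols = 0, nmatch = 0;
    int qe = bi, re = bj;
    while (i > 0 && j > 0) {
        int k = i * (n + 1) + j;
        unsigned char tb = TB[k];
        if (tb == 0 || H[k] == 0.0) break;
        if (tb == 1) {
            if (q[i - 1] == r[j - 1]) ++nmatch;
            --i; --j; ++ncols;
        } else if (tb == 2) { --i; ++ncols; }
        else { --j; ++ncols; }
    }
    res.score = best;
    res.q_start = i + 1; res.q_end = qe;
    res.r_start = j + 1; res.r_end = re;
    res.n_cols = ncols; res.n_match = nmatch;
    return res;
}

// Best local alignment of one query against each reference.
// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, CharacterVector refs,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
    R_xlen_t n = refs.size();
    NumericVector score(n);
    IntegerVector qs(n), qe(n), rs(n), re(n), ncols(n), nmatch(n);
    for (R_xlen_t t = 0; t < n; ++t) {
        SWResult r = sw_align(query, as<std::string>(refs[t]),
                              match, mismatch, gap_open, gap_extend);
        score[t] = r.score;
        qs[t] = r.q_start; qe[t] = r.q_end;
        rs[t] = r.r_start; re[t] = r.r_end;
        ncols[t] = r.n_cols; nmatch[t] = r.n_match;
    }
    return DataFrame::create(_["score"] = score,
                             _["q_start"] = qs, _["q_end"] = qe,
                             _["r_start"] = rs, _["r_end"] = re,
                             _["n_cols"] = ncols, _["n_match"] = nmatch);
}

// Global (Needleman-Wunsch) alignment of b against a, linear gap cost,
// returning the two gapped strings.  Used for consensus polishing where the
// first sequence is the medoid scaffold.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      double match, double mismatch, double gap) {
    const int m = (int)a.size(), n = (int)b.size();
    std::vector<double> H((m + 1) * (n + 1));
    std::vector<unsigned char> TB((m + 1) * (n + 1)); // 1 diag, 2 up, 3 left
    for (int i = 0; i <= m; ++i) { H[i * (n + 1)] = i * gap; TB[i * (n + 1)] = 2; }
    for (int j = 0; j <= n; ++j) { H[j] = j * gap; TB[j] = 3; }
    TB[0] = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int k = i * (n + 1) + j;
            double d = H[k - (n + 2)] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
            double up = H[k - (n + 1)] + gap;
            double lf = H[k - 1] + gap;
            // prefer diagonal on ties for a deterministic, compact alignment
            if (d >= up && d >= lf) { H[k] = d; TB[k] = 1; }
            else if (up >= lf) { H[k] = up; TB[k] = 2; }
            else { H[k] = lf; TB[k] = 3; }
        }
    }
    std::string ga, gb;
    int i = m, j = n;
    while (i > 0 || j > 0) {
        unsigned char tb = TB[i * (n + 1) + j];
        if (tb == 1) { ga += a[i - 1]; gb += b[j - 1]; --i; --j; }
        else if (tb == 2) { ga += a[i - 1]; gb += '-'; --i; }
        else { ga += '-'; gb += b[j - 1]; --j; }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    return List::create(_["a"] = ga, _["b"] = gb,
                        _["score"] = H[m * (n + 1) + n]);
}

// Per-base corruption: deletion, then substitution, then insertion after the
// base, at independent per-base rates.  Uses R's RNG so set.seed() governs.
// [[Rcpp::export]]
CharacterVector cpp_corrupt(CharacterVector seqs, double sub_rate,
                            double ins_rate, double del_rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t t = 0; t < n; ++t) {
        std::string s = as<std::string>(seqs[t]);
        std::string r;
        r.reserve(s.size() + 8);
        for (size_t i = 0; i < s.size(); ++i) {
            if (del_rate > 0 && unif_rand() < del_rate) {
                // base dropped
            } else if (sub_rate > 0 && unif_rand() < sub_rate) {
                char c = s[i], nc;
                do { nc = bases[(int)(unif_rand() * 4) % 4]; } while (nc == c);
                r += nc;
            } else {
                r += s[i];
            }
            if (ins_rate > 0 && unif_rand() < ins_rate) {
                r += bases[(int)(unif_rand() * 4) % 4];
            }
        }
        out[t] = r;
    }
    return out;
}
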