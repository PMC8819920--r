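#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Draw n random DNA strings of one length whose pairwise Levenshtein
// distance is >= 2.  Equal-length strings at distance 1 differ by exactly
// one substitution, so it suffices to reject any candidate that is an
// accepted string or one of its substitution neighbours.  Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_separated_umis(int n, int len) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::unordered_set<std::string> ball; // accepted + substitution 1-balls
    std::vector<std::string> out;
    out.reserve(n);
    long attempts = 0, maxAttempts = 1000L * n + 1000L;
    while ((int)out.size() < n) {
        if (++attempts > maxAttempts)
            stop("UMI space too dense: cannot draw %d separated %d-mers",
                 n, len);
        std::string s(len, 'A');
        for (int i = 0; i < len; ++i)
            s[i] = bases[(int)(unif_rand() * 4) % 4];
        if (ball.count(s)) continue;
        out.push_back(s);
        ball.insert(s);
        for (int i = 0; i < len; ++i)
            for (int b = 0; b < 4; ++b) {
                if (bases[b] == s[i]) continue;
                std::string t = s;
                t[i] = bases[b];
                ball.insert(t);
            }
    }
    return wrap(out);
}
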