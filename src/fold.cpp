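#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Watson-Crick plus G.U wobble pairing on RNA alphabet (T treated as U).
static inline bool can_pair(char a, char b) {
    if (a == 'T') a = 'U';
    if (b == 'T') b = 'U';
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pair secondary structure (no pseudoknots, hairpin loop >= min_loop)
// by dynamic programming over intervals. For [i, j] either i is unpaired or i
// pairs with some k >= i + min_loop + 1. Intervals too short to hold a pair keep
// score 0. Traceback resolves the smallest i first and, when several partners k
// are optimal, takes the largest k; pairing i is preferred over leaving it
// unpaired whenever both reach the optimum.
// [[Rcpp::export(name = ".fold_maxpair_cpp")]]
List fold_maxpair_cpp(std::string seq, int min_loop = 3) {
    const int n = (int) seq.size();
    std::string db(n, '.');
    IntegerVector pairing(n, NA_INTEGER);
    if (n < min_loop + 2)
        return List::create(_["structure"] = db, _["pairs"] = 0,
                            _["pairing"] = pairing);

    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    // score of interval [a, b], 0 when empty/invalid
    #define SC(a, b) (((a) <= (b) && (a) >= 0 && (b) < n) ? M[(a)][(b)] : 0)

    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = SC(i + 1, j);
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                int cand = 1 + SC(i + 1, k - 1) + SC(k + 1, j);
                if (cand > best) best = cand;
            }
            M[i][j] = best;
        }
    }

    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i + 1 < min_loop + 2 || M[i][j] == 0) continue;
        bool paired = false;
        for (int k = j; k >= i + min_loop + 1; --k) {
            if (!can_pair(seq[i], seq[k])) continue;
            if (1 + SC(i + 1, k - 1) + SC(k + 1, j) == M[i][j]) {
                db[i] = '(';
                db[k] = ')';
                pairing[i] = k + 1;  // 1-based partners
                pairing[k] = i + 1;
                if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
                stack.push_back(std::make_pair(i + 1, k - 1));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    #undef SC

    return List::create(_["structure"] = db,
                        _["pairs"] = M[0][n - 1],
                        _["pairing"] = pairing);
}
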