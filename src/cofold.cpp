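#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Pair weights of the reference backend: G:C = 3, A:U = 2, G:U = 1.
// Any letter outside A/C/G/U (in particular N) never pairs.
static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
    return 0;
}

// Base-pair maximization (Nussinov-style) on the concatenation of the two
// strands.  Intramolecular pairs require a hairpin loop of >= 3 unpaired
// bases; no loop-size constraint applies across the strand break, so the
// two molecules may hybridize end-on.  Tie-breaking in the traceback is
// deterministic: position i pairs with the smallest partner that achieves
// the optimum; it is left unpaired only when no pairing does.  This keeps
// co-optimal helices flush (stem-proximal), which downstream junction
// detection relies on.
//
// seq:   concatenated sequence (uppercase A/C/G/U/N)
// len_m: length of the first (mRNA-side) strand
// Returns partner vector (1-based, 0 = unpaired) and the total pair weight.
// [[Rcpp::export(name = ".cofold_dp")]]
List cofold_dp(std::string seq, int len_m) {
    const int L = (int) seq.size();
    if (L < 1) stop("empty sequence");

    std::vector<std::vector<int> > E(L, std::vector<int>(L, 0));

    auto weight = [&](int i, int j) -> int {
        int w = pair_weight(seq[i], seq[j]);
        if (w == 0) return 0;
        bool same_strand = (i < len_m) == (j < len_m);
        if (same_strand && (j - i - 1) < 3) return 0;
        return w;
    };
    auto e = [&](int i, int j) -> int { return (i > j) ? 0 : E[i][j]; };

    for (int span = 1; span < L; ++span) {
        for (int i = 0; i + span < L; ++i) {
            int j = i + span;
            int best = E[i + 1 > j ? j : i + 1][j]; // i+1 <= j always here
            for (int k = i + 1; k <= j; ++k) {
                int w = weight(i, k);
                if (w == 0) continue;
                int cand = w + e(i + 1, k - 1) + e(k + 1, j);
                if (cand > best) best = cand;
            }
            E[i][j] = best;
        }
    }

    IntegerVector partner(L, 0);
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, L - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        bool paired = false;
        for (int k = i + 1; k <= j; ++k) { // smallest admissible partner
            int w = weight(i, k);
            if (w == 0) continue;
            if (w + e(i + 1, k - 1) + e(k + 1, j) == E[i][j]) {
                partner[i] = k + 1;
                partner[k] = i + 1;
                stack.push_back(std::make_pair(i + 1, k - 1));
                stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired)                       // only then leave i unpaired
            stack.push_back(std::make_pair(i + 1, j));
    }

    return List::create(_["partner"] = partner,
                        _["score"]   = (L >= 2 ? E[0][L - 1] : 0));
}
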