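#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Base-pair maximisation (Nussinov) secondary-structure prediction.
// Canonical Watson-Crick pairs plus G:U wobble; minimum hairpin loop size
// is configurable (default 3 unpaired bases). Input may be DNA or RNA
// characters; T and U are equivalent. Returns the 1-based pairing partner
// per position (0 = unpaired) from a standard traceback of one optimal
// structure (deterministic tie-break: bifurcation checked last, pairing
// i..j preferred over leaving j unpaired).

static inline bool can_pair(char a, char b) {
    if (a == 'U') a = 'T';
    if (b == 'U') b = 'T';
    return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(std::string seq, int min_loop = 3) {
    int n = seq.size();
    IntegerVector partner(n, 0);
    if (n < 2) return partner;
    for (auto &c : seq) c = toupper(c);
    std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i][j - 1];  // j unpaired
            if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
                int inner = (i + 1 <= j - 1) ? M[i + 1][j - 1] : 0;
                best = std::max(best, inner + 1);
            }
            // bifurcation: j pairs with some k in (i, j)
            for (int k = i + 1; k < j; ++k) {
                if (can_pair(seq[k], seq[j]) && j - k > min_loop) {
                    int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
                    int left = (k - 1 >= i) ? M[i][k - 1] : 0;
                    best = std::max(best, left + inner + 1);
                }
            }
            M[i][j] = best;
        }
    }
    // traceback
    std::stack<std::pair<int, int>> st;
    st.push({0, n - 1});
    while (!st.empty()) {
        auto [i, j] = st.top();
        st.pop();
        if (i >= j || j - i <= min_loop) continue;
        if (M[i][j] == M[i][j - 1]) {
            st.push({i, j - 1});
            continue;
        }
        if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
            int inner = (i + 1 <= j - 1) ? M[i + 1][j - 1] : 0;
            if (M[i][j] == inner + 1) {
                partner[i] = j + 1;
                partner[j] = i + 1;
                st.push({i + 1, j - 1});
                continue;
            }
        }
        bool done = false;
        for (int k = i + 1; k < j && !done; ++k) {
            if (can_pair(seq[k], seq[j]) && j - k > min_loop) {
                int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
                int left = (k - 1 >= i) ? M[i][k - 1] : 0;
                if (M[i][j] == left + inner + 1) {
                    partner[k] = j + 1;
                    partner[j] = k + 1;
                    if (k - 1 > i) st.push({i, k - 1});
                    st.push({k + 1, j - 1});
                    done = true;
                }
            }
        }
    }
    return partner;
}
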