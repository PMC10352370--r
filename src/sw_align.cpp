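// Smith-Waterman local alignment with affine gaps over integer-coded
// residue sequences and an arbitrary substitution matrix. A gap of length k
// costs gap_open + k * gap_extend. Returns the optimal score and the
// 0-based half-open spans of the best local alignment (traceback from the
// first highest-scoring cell).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, IntegerMatrix mat,
              int gap_open, int gap_extend) {
    const int n = q.size(), m = s.size();
    const long long NEG = -1000000000LL;
    const int open_cost = gap_open + gap_extend;  // first gap residue

    const size_t W = (size_t)m + 1;
    std::vector<long long> M((size_t)(n + 1) * W, 0),
        X((size_t)(n + 1) * W, NEG), Y((size_t)(n + 1) * W, NEG);

    long long best = 0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        M[i * W] = 0; X[i * W] = NEG; Y[i * W] = NEG;
        for (int j = 1; j <= m; ++j) {
            const size_t at = i * W + j, up = (i - 1) * W + j,
                left = i * W + (j - 1), diag = (i - 1) * W + (j - 1);
            X[at] = std::max(M[up] - open_cost, X[up] - gap_extend);
            Y[at] = std::max(M[left] - open_cost, Y[left] - gap_extend);
            long long sub = mat(q[i - 1], s[j - 1]);
            long long mm = std::max(std::max(M[diag], X[diag]), Y[diag]) + sub;
            if (mm < 0) mm = 0;
            M[at] = mm;
            if (mm > best) { best = mm; bi = i; bj = j; }
        }
    }

    // traceback from (bi, bj), state M
    int i = bi, j = bj, state = 1;  // 1=M 2=X 3=Y
    while (i > 0 && j > 0) {
        const size_t at = i * W + j, up = (i - 1) * W + j,
            left = i * W + (j - 1), diag = (i - 1) * W + (j - 1);
        if (state == 1) {
            if (M[at] == 0) break;
            long long sub = mat(q[i - 1], s[j - 1]);
            if (M[at] == M[diag] + sub) state = 1;
            else if (M[at] == X[diag] + sub) state = 2;
            else state = 3;
            --i; --j;
        } else if (state == 2) {
            state = (X[at] == M[up] - open_cost) ? 1 : 2;
            --i;
        } else {
            state = (Y[at] == M[left] - open_cost) ? 1 : 3;
            --j;
        }
    }
    int qs = i, ss = j, qe = bi, se = bj;
    if (best == 0) { qs = qe = ss = se = 0; }
    return List::create(_["score"] = (double)best,
                        _["q_start"] = qs, _["q_end"] = qe,
                        _["s_start"] = ss, _["s_end"] = se);
}
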