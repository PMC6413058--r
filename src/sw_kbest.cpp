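#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>
using namespace Rcpp;

// k best non-overlapping local alignments (Waterman-Eggert declumping).
//
// Linear gap model: every gapped position costs `gap`. Bases are encoded
// 0..3 for A,C,G,T; any negative code (ambiguity) mismatches everything,
// including itself. Masked subject columns are forced to H = 0, so no
// reported alignment can consume a masked subject base; after each pass
// the reported subject interval is added to the mask.
//
// The DP matrix is kept column-major with per-column maxima. After a
// hit's interval is masked, only columns from the interval onward are
// recomputed, stopping as soon as a recomputed column equals its
// previous value (all later columns then cannot change) - the standard
// declumping recurrence at a fraction of the full-matrix cost.
//
// Tie-breaks are deterministic: the best cell is the maximum-score cell
// with the smallest subject end, then smallest query end; traceback
// prefers diagonal over up (consume query base) over left.
//
// Returns a matrix with one row per hit:
//   score, s_start, s_end, q_start, q_end   (all 1-based inclusive)
// [[Rcpp::export]]
IntegerMatrix sw_kbest_c(IntegerVector query, IntegerVector subject,
                         int match, int mismatch, int gap, int k,
                         int min_score,
                         IntegerVector mask_start, IntegerVector mask_end) {
    const int m = query.size(), n = subject.size();
    if (m < 1 || n < 1)
        stop("query and subject must be non-empty sequences");
    if (min_score < 1) min_score = 1;
    std::vector<int> q(m), s(n);
    for (int i = 0; i < m; ++i) q[i] = query[i];
    for (int j = 0; j < n; ++j) s[j] = subject[j];
    std::vector<char> masked(n + 1, 0);
    for (int t = 0; t < mask_start.size(); ++t) {
        int lo = mask_start[t], hi = mask_end[t];
        if (lo < 1) lo = 1;
        if (hi > n) hi = n;
        for (int j = lo; j <= hi; ++j) masked[j] = 1;
    }

    const int mp1 = m + 1;
    std::vector<int> H((size_t)(n + 1) * mp1, 0);   // column-major
    std::vector<int> col_max(n + 1, 0), col_arg(n + 1, 0);
    std::vector<int> tmp(mp1, 0);

    // compute column j into `out` given the previous column `prev`;
    // fills colmax/colarg (smallest i wins ties)
    auto computeCol = [&](int j, const int *prev, int *out,
                          int &cmax, int &carg) {
        out[0] = 0;
        cmax = 0; carg = 0;
        if (masked[j]) {
            std::memset(out, 0, sizeof(int) * mp1);
            return;
        }
        const int sj = s[j - 1];
        for (int i = 1; i <= m; ++i) {
            const int qi = q[i - 1];
            int h = prev[i - 1] + ((qi >= 0 && qi == sj) ? match : mismatch);
            const int up = out[i - 1] - gap;
            if (up > h) h = up;
            const int left = prev[i] - gap;
            if (left > h) h = left;
            if (h < 0) h = 0;
            out[i] = h;
            if (h > cmax) { cmax = h; carg = i; }
        }
    };

    // full initial sweep
    for (int j = 1; j <= n; ++j)
        computeCol(j, &H[(size_t)(j - 1) * mp1], &H[(size_t)j * mp1],
                   col_max[j], col_arg[j]);

    std::vector<std::array<int, 5>> hits;
    for (int pass = 0; pass < k; ++pass) {
        int best = 0, bj = 0;
        for (int j = 1; j <= n; ++j)
            if (col_max[j] > best) { best = col_max[j]; bj = j; }
        if (best < min_score) break;
        int bi = col_arg[bj];

        // traceback from (bi, bj) to the first zero cell
        int i = bi, j = bj;
        while (i > 0 && j > 0) {
            const int h = H[(size_t)j * mp1 + i];
            if (h <= 0) break;
            const int qi = q[i - 1];
            const int sc = (qi >= 0 && qi == s[j - 1]) ? match : mismatch;
            if (H[(size_t)(j - 1) * mp1 + (i - 1)] + sc == h) {
                --i; --j;
            } else if (H[(size_t)j * mp1 + (i - 1)] - gap == h) {
                --i;
            } else if (H[(size_t)(j - 1) * mp1 + i] - gap == h) {
                --j;
            } else {
                break;
            }
        }
        const int ss = j + 1, se = bj, qs = i + 1, qe = bi;
        hits.push_back({best, ss, se, qs, qe});
        if ((int)hits.size() == k) break;
        for (int jj = ss; jj <= se; ++jj) masked[jj] = 1;

        // recompute from the masked interval onward until convergence
        for (int jj = ss; jj <= n; ++jj) {
            int cmax, carg;
            computeCol(jj, &H[(size_t)(jj - 1) * mp1], tmp.data(),
                       cmax, carg);
            int *cur = &H[(size_t)jj * mp1];
            if (jj > se &&
                std::memcmp(tmp.data(), cur, sizeof(int) * mp1) == 0)
                break;
            std::memcpy(cur, tmp.data(), sizeof(int) * mp1);
            col_max[jj] = cmax; col_arg[jj] = carg;
        }
    }

    IntegerMatrix out((int)hits.size(), 5);
    for (size_t r = 0; r < hits.size(); ++r)
        for (int c = 0; c < 5; ++c) out((int)r, c) = hits[r][c];
    colnames(out) = CharacterVector::create("score", "s_start", "s_end",
                                            "q_start", "q_end");
    return out;
}
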