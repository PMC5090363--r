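#include <Rcpp.h>
#include <vector>
#include "bsutil.h"

using namespace Rcpp;

// Semi-global (free end gap) affine alignment of an amplicon read against a
// tRNA reference, with C/T treated as equivalent at reference cytosines so a
// read's conversion state cannot bias its placement. Returns the read base
// aligned over every reference position ('-' where the reference position is
// deleted or outside the aligned span), the score, and the converted-identity
// fraction over aligned reference columns.

static inline double score3(double m, double x, double y) {
    return std::max(m, std::max(x, y));
}

// [[Rcpp::export]]
List align_amplicon_cpp(std::string read, std::string ref,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
    int n = (int)ref.size(), m = (int)read.size();
    const double NEG = -1e18;
    // M: ref[i] aligned to read[j]; X: gap in read (ref consumed);
    // Y: gap in ref (read consumed)
    std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<double> > X(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<double> > Y(n + 1, std::vector<double>(m + 1, NEG));
    M[0][0] = 0.0;
    for (int i = 1; i <= n; ++i) X[i][0] = 0.0;  // free leading ref overhang
    for (int j = 1; j <= m; ++j) Y[0][j] = 0.0;  // free leading read overhang

    double go = gap_open + gap_extend;  // cost of the first gapped base
    for (int i = 1; i <= n; ++i) {
        char rb = ref[i - 1];
        for (int j = 1; j <= m; ++j) {
            char qb = read[j - 1];
            bool ok = (qb == rb) || (rb == 'C' && (qb == 'C' || qb == 'T'));
            double s = ok ? match : mismatch;
            M[i][j] = score3(M[i - 1][j - 1], X[i - 1][j - 1], Y[i - 1][j - 1]) + s;
            X[i][j] = std::max(score3(M[i - 1][j], NEG, Y[i - 1][j]) + go,
                               X[i - 1][j] + gap_extend);
            Y[i][j] = std::max(score3(M[i][j - 1], X[i][j - 1], NEG) + go,
                               Y[i][j - 1] + gap_extend);
        }
    }

    // free trailing gaps: best cell on the last row or last column
    int bi = n, bj = m;
    double best = NEG;
    for (int j = 0; j <= m; ++j) {
        double v = score3(M[n][j], X[n][j], Y[n][j]);
        if (v >= best) { best = v; bi = n; bj = j; }
    }
    for (int i = 0; i <= n; ++i) {
        double v = score3(M[i][m], X[i][m], Y[i][m]);
        if (v > best) { best = v; bi = i; bj = m; }
    }

    // traceback from (bi, bj) to a boundary
    std::string calls(n, '-');
    int aligned_cols = 0, matched_cols = 0;
    int i = bi, j = bj;
    int state;  // 0 = M, 1 = X, 2 = Y
    {
        double vm = M[i][j], vx = X[i][j], vy = Y[i][j];
        state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
    }
    while (i > 0 && j > 0) {
        if (state == 0) {
            char rb = ref[i - 1], qb = read[j - 1];
            bool ok = (qb == rb) || (rb == 'C' && (qb == 'C' || qb == 'T'));
            double s = ok ? match : mismatch;
            calls[i - 1] = qb;
            ++aligned_cols;
            if (ok) ++matched_cols;
            double prev = M[i][j] - s;
            double vm = M[i - 1][j - 1], vx = X[i - 1][j - 1];
            state = (vm == prev) ? 0 : ((vx == prev) ? 1 : 2);
            --i; --j;
        } else if (state == 1) {
            // reference base skipped by the read: a deletion => gap call
            double cur = X[i][j];
            --i;
            if (X[i][j] + gap_extend == cur && X[i][j] > NEG / 2) state = 1;
            else {
                double prev = cur - go;
                double vm = M[i][j], vy = Y[i][j];
                state = (vm == prev) ? 0 : ((vy == prev) ? 2 : 1);
            }
        } else {
            double cur = Y[i][j];
            --j;
            if (Y[i][j] + gap_extend == cur && Y[i][j] > NEG / 2) state = 2;
            else {
                double prev = cur - go;
                double vm = M[i][j], vx = X[i][j];
                state = (vm == prev) ? 0 : ((vx == prev) ? 1 : 2);
            }
        }
    }

    double ident = aligned_cols > 0 ? (double)matched_cols / aligned_cols : 0.0;
    return List::create(_["score"] = best, _["calls"] = String(calls),
                        _["aligned_cols"] = aligned_cols,
                        _["identity"] = ident);
}
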