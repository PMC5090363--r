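#include <Rcpp.h>
#include "bsutil.h"

using namespace Rcpp;

// Per-position informative-base counting. Reads arrive in Watson orientation:
// original-top reads report C (unconverted) vs T (converted) at Watson C
// positions; original-bottom reads report G vs A at Watson G positions
// (the Crick-strand cytosines). Overlapping mates of one pair count once,
// mate 1 taking precedence. Other bases are ignored.
// [[Rcpp::export]]
List pileup_cpp(CharacterVector seqs, IntegerVector comp, LogicalVector is_ot,
                IntegerVector p1, CharacterVector w1,
                IntegerVector p2, CharacterVector w2) {
    int ncomp = seqs.size();
    std::vector<std::string> refs;
    std::vector<IntegerVector> unconv, conv;
    for (int c = 0; c < ncomp; ++c) {
        refs.push_back(as<std::string>(seqs[c]));
        unconv.push_back(IntegerVector((int)refs[c].size()));
        conv.push_back(IntegerVector((int)refs[c].size()));
    }

    int n = comp.size();
    for (int i = 0; i < n; ++i) {
        int c = comp[i] - 1;
        if (c < 0 || c >= ncomp) stop("alignment references unknown component");
        bool ot = (is_ot[i] == TRUE);
        std::string s1 = as<std::string>(w1[i]);
        std::string s2 = as<std::string>(w2[i]);
        int a1 = p1[i], a2 = p2[i];
        int e1 = a1 + (int)s1.size();  // mate-1 exclusive end, for overlap rule
        const std::string &ref = refs[c];
        for (int mate = 0; mate < 2; ++mate) {
            const std::string &s = mate ? s2 : s1;
            int left = mate ? a2 : a1;
            for (int j = 0; j < (int)s.size(); ++j) {
                int pos = left + j;
                if (pos < 0 || pos >= (int)ref.size()) continue;
                if (mate == 1 && pos >= a1 && pos < e1) continue;  // mate-1 wins
                char rb = ref[pos], bb = s[j];
                if (ot && rb == 'C') {
                    if (bb == 'C') ++unconv[c][pos];
                    else if (bb == 'T') ++conv[c][pos];
                } else if (!ot && rb == 'G') {
                    if (bb == 'G') ++unconv[c][pos];
                    else if (bb == 'A') ++conv[c][pos];
                }
            }
        }
    }

    List out(ncomp);
    for (int c = 0; c < ncomp; ++c)
        out[c] = List::create(_["unconverted"] = unconv[c],
                              _["converted"] = conv[c]);
    return out;
}

// Terminal trimming bounds: 1-based [start, end] of the kept window after
// capping at max_len from the 5' end and stripping maximal terminal runs of
// bases below min_qual. start > end means the read is discarded.
// [[Rcpp::export]]
IntegerMatrix trim_bounds_cpp(CharacterVector quals, int max_len, int min_qual) {
    int n = quals.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        std::string q = as<std::string>(quals[i]);
        int L = std::min((int)q.size(), max_len);
        int s = 0, e = L - 1;
        for (int j = 0; j < L; ++j) {
            if (q[j] < '!') stop("quality character below '!' (not Phred+33)");
        }
        while (s < L && (q[s] - 33) < min_qual) ++s;
        while (e >= s && (q[e] - 33) < min_qual) --e;
        out(i, 0) = s + 1;
        out(i, 1) = e + 1;  // s+1 > e+1 when nothing survives
    }
    return out;
}
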