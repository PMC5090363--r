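#include <Rcpp.h>
#include "bsutil.h"

using namespace Rcpp;

// First-order Markov sampler used by the reference builder. After a C the
// G-transition probability is scaled by the CpG enrichment factor (capped),
// the other bases renormalised; factor 1 collapses to i.i.d. sampling.
// Draws come from R's RNG so sequences are reproducible under set.seed().
// [[Rcpp::export]]
String markov_seq_cpp(int n, NumericVector p_base, NumericVector p_after_c) {
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    std::string out(n, 'A');
    int prev = -1;
    for (int i = 0; i < n; ++i) {
        const NumericVector &p = (prev == 1) ? p_after_c : p_base;
        double u = unif_rand(), acc = 0.0;
        int b = 3;
        for (int j = 0; j < 4; ++j) {
            acc += p[j];
            if (u < acc) { b = j; break; }
        }
        out[i] = BASES[b];
        prev = b;
    }
    return String(out);
}

static void convert_template(std::string &tmpl, bool is_ot, int start, int insert,
                             const LogicalVector &meth_plus,
                             const LogicalVector &meth_minus,
                             double failure, double overconv) {
    // tmpl is the original strand 5'->3': the Watson fragment for OT, its
    // reverse complement for OB. Cytosines on the template map to Watson
    // coordinates start+i (OT) or start+insert-1-i (OB).
    for (int i = 0; i < (int)tmpl.size(); ++i) {
        if (tmpl[i] != 'C') continue;
        int wpos = is_ot ? (start + i) : (start + insert - 1 - i);
        bool meth = is_ot ? (meth_plus[wpos] == TRUE) : (meth_minus[wpos] == TRUE);
        if (meth) {
            if (overconv > 0 && unif_rand() < overconv) tmpl[i] = 'T';
        } else {
            if (!(failure > 0 && unif_rand() < failure)) tmpl[i] = 'T';
        }
    }
}

static void add_errors(std::string &s, double rate) {
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    if (rate <= 0) return;
    for (size_t i = 0; i < s.size(); ++i) {
        if (unif_rand() < rate) {
            char b;
            do {
                b = BASES[(int)(unif_rand() * 4) & 3];
            } while (b == s[i]);
            s[i] = b;
        }
    }
}

// Bisulfite-convert fragments and emit both mates (sequenced orientation).
// [[Rcpp::export]]
List simulate_pairs_cpp(CharacterVector seqs, IntegerVector comp,
                        IntegerVector start, IntegerVector insert,
                        LogicalVector is_ot, List meth_plus, List meth_minus,
                        double failure_rate, double overconversion_rate,
                        double seq_error_rate, int read_length) {
    int n = comp.size();
    std::vector<std::string> refs;
    for (int i = 0; i < seqs.size(); ++i)
        refs.push_back(as<std::string>(seqs[i]));

    CharacterVector out1(n), out2(n);
    for (int i = 0; i < n; ++i) {
        int c = comp[i] - 1;
        int ins = insert[i], st = start[i];
        std::string frag = refs[c].substr(st, ins);
        bool ot = (is_ot[i] == TRUE);
        std::string tmpl = ot ? frag : revcomp(frag);
        LogicalVector mp = meth_plus[c], mm = meth_minus[c];
        convert_template(tmpl, ot, st, ins, mp, mm, failure_rate,
                         overconversion_rate);
        std::string m1 = tmpl.substr(0, read_length);
        std::string m2 = revcomp(tmpl.substr(ins - read_length, read_length));
        add_errors(m1, seq_error_rate);
        add_errors(m2, seq_error_rate);
        out1[i] = m1;
        out2[i] = m2;
    }
    return List::create(_["seq1"] = out1, _["seq2"] = out2);
}
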