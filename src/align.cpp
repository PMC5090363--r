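#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <vector>
#include "bsutil.h"

using namespace Rcpp;

// Seed-and-extend bisulfite aligner over the two reduced-alphabet references
// (C->T for original-top, G->A for original-bottom). Positions are packed as
// comp * 2^32 + pos into doubles (exact below 2^53).

static const double PACK = 4294967296.0;

struct SeedTable {
    std::vector<double> codes;  // sorted k-mer codes (duplicated per occurrence)
    std::vector<double> pos;    // parallel packed positions
};

static void build_table(const std::vector<std::string> &seqs, int k,
                        SeedTable &tab) {
    std::vector<std::pair<double, double> > entries;
    for (size_t c = 0; c < seqs.size(); ++c) {
        const std::string &s = seqs[c];
        if ((int)s.size() < k) continue;
        uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int b = base_code(s[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint64_t)b) & mask;
            if (++valid >= k) {
                size_t start = i - k + 1;
                entries.push_back(std::make_pair((double)code,
                                                 (double)c * PACK + (double)start));
            }
        }
    }
    std::sort(entries.begin(), entries.end());
    tab.codes.resize(entries.size());
    tab.pos.resize(entries.size());
    for (size_t i = 0; i < entries.size(); ++i) {
        tab.codes[i] = entries[i].first;
        tab.pos[i] = entries[i].second;
    }
}

// [[Rcpp::export]]
List build_index_cpp(CharacterVector seqs, int k) {
    std::vector<std::string> ct, ga;
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        ct.push_back(reduce_ct(s));
        ga.push_back(reduce_ga(s));
    }
    SeedTable tct, tga;
    build_table(ct, k, tct);
    build_table(ga, k, tga);
    CharacterVector ct_seqs(ct.size()), ga_seqs(ga.size());
    for (size_t i = 0; i < ct.size(); ++i) {
        ct_seqs[i] = ct[i];
        ga_seqs[i] = ga[i];
    }
    return List::create(
        _["k"] = k,
        _["ct_codes"] = NumericVector(tct.codes.begin(), tct.codes.end()),
        _["ct_pos"] = NumericVector(tct.pos.begin(), tct.pos.end()),
        _["ga_codes"] = NumericVector(tga.codes.begin(), tga.codes.end()),
        _["ga_pos"] = NumericVector(tga.pos.begin(), tga.pos.end()),
        _["ct_seqs"] = ct_seqs,
        _["ga_seqs"] = ga_seqs);
}

struct Cand { int comp; int left; int mm; };

static bool code_at(const std::string &s, size_t off, int k, uint64_t &code) {
    code = 0;
    for (int j = 0; j < k; ++j) {
        int b = base_code(s[off + j]);
        if (b < 0) return false;
        code = (code << 2) | (uint64_t)b;
    }
    return true;
}

static int count_mm(const std::string &read, const std::string &ref, int left,
                    int cap) {
    int mm = 0;
    for (size_t j = 0; j < read.size(); ++j) {
        if (read[j] != ref[left + j]) {
            if (++mm > cap) return mm;
        }
    }
    return mm;
}

// seed candidate loci for one reduced read against one seed table, then
// extend ungapped against the reduced reference; keeps mm <= max_mm
static void candidates(const std::string &read,
                       const std::vector<double> &codes,
                       const std::vector<double> &pos,
                       const std::vector<std::string> &refs, int k,
                       int max_mm, int max_seeds, int max_hits,
                       std::vector<Cand> &out) {
    int len = (int)read.size();
    if (len < k) return;
    std::vector<std::pair<int, int> > seen;  // (comp,left) dedup
    int n_seeds = 0;
    for (int off = 0; off + k <= len && n_seeds < max_seeds; off += k, ++n_seeds) {
        uint64_t code;
        if (!code_at(read, off, k, code)) continue;
        double dc = (double)code;
        std::vector<double>::const_iterator lo =
            std::lower_bound(codes.begin(), codes.end(), dc);
        std::vector<double>::const_iterator hi =
            std::upper_bound(codes.begin(), codes.end(), dc);
        if (hi - lo > max_hits) continue;  // uninformative repeat seed
        for (std::vector<double>::const_iterator it = lo; it != hi; ++it) {
            double packed = pos[it - codes.begin()];
            int comp = (int)(packed / PACK);
            int p = (int)(packed - comp * PACK);
            int left = p - off;
            if (left < 0 || left + len > (int)refs[comp].size()) continue;
            std::pair<int, int> key(comp, left);
            if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
            seen.push_back(key);
            int mm = count_mm(read, refs[comp], left, max_mm);
            if (mm <= max_mm) {
                Cand c; c.comp = comp; c.left = left; c.mm = mm;
                out.push_back(c);
            }
        }
    }
}

struct PairHit {
    int comp, strand, p1, p2, mm1, mm2;  // strand: 1 = OT, 0 = OB
};

// [[Rcpp::export]]
DataFrame align_pairs_cpp(List index, CharacterVector seq1, CharacterVector seq2,
                          int max_mm, int insert_min, int insert_max,
                          int max_seeds, int max_hits) {
    int k = as<int>(index["k"]);
    NumericVector ctc = index["ct_codes"], ctp = index["ct_pos"];
    NumericVector gac = index["ga_codes"], gap = index["ga_pos"];
    std::vector<double> ct_codes(ctc.begin(), ctc.end());
    std::vector<double> ct_pos(ctp.begin(), ctp.end());
    std::vector<double> ga_codes(gac.begin(), gac.end());
    std::vector<double> ga_pos(gap.begin(), gap.end());
    CharacterVector cts = index["ct_seqs"], gas = index["ga_seqs"];
    std::vector<std::string> ct_refs, ga_refs;
    for (int i = 0; i < cts.size(); ++i) {
        ct_refs.push_back(as<std::string>(cts[i]));
        ga_refs.push_back(as<std::string>(gas[i]));
    }

    int n = seq1.size();
    IntegerVector o_comp(n), o_p1(n), o_p2(n), o_nm1(n), o_nm2(n), o_nbest(n);
    LogicalVector o_mapped(n), o_unique(n), o_ot(n);

    for (int i = 0; i < n; ++i) {
        std::string m1 = as<std::string>(seq1[i]);
        std::string m2 = as<std::string>(seq2[i]);
        int len1 = (int)m1.size(), len2 = (int)m2.size();
        int min_ins = std::max(insert_min, std::max(len1, len2));

        std::vector<PairHit> hits;

        // original-top: mate1 forward on C->T reference, mate2 reverse
        {
            std::vector<Cand> c1, c2;
            candidates(reduce_ct(m1), ct_codes, ct_pos, ct_refs, k, max_mm,
                       max_seeds, max_hits, c1);
            candidates(reduce_ct(revcomp(m2)), ct_codes, ct_pos, ct_refs, k,
                       max_mm, max_seeds, max_hits, c2);
            for (size_t a = 0; a < c1.size(); ++a)
                for (size_t b = 0; b < c2.size(); ++b) {
                    if (c1[a].comp != c2[b].comp) continue;
                    int ins = c2[b].left + len2 - c1[a].left;
                    if (ins < min_ins || ins > insert_max) continue;
                    PairHit h; h.comp = c1[a].comp; h.strand = 1;
                    h.p1 = c1[a].left; h.p2 = c2[b].left;
                    h.mm1 = c1[a].mm; h.mm2 = c2[b].mm;
                    hits.push_back(h);
                }
        }
        // original-bottom: mate1 reverse on G->A reference, mate2 forward
        {
            std::vector<Cand> c1, c2;
            candidates(reduce_ga(revcomp(m1)), ga_codes, ga_pos, ga_refs, k,
                       max_mm, max_seeds, max_hits, c1);
            candidates(reduce_ga(m2), ga_codes, ga_pos, ga_refs, k, max_mm,
                       max_seeds, max_hits, c2);
            for (size_t a = 0; a < c1.size(); ++a)
                for (size_t b = 0; b < c2.size(); ++b) {
                    if (c1[a].comp != c2[b].comp) continue;
                    int ins = c1[a].left + len1 - c2[b].left;
                    if (ins < min_ins || ins > insert_max) continue;
                    PairHit h; h.comp = c1[a].comp; h.strand = 0;
                    h.p1 = c1[a].left; h.p2 = c2[b].left;
                    h.mm1 = c1[a].mm; h.mm2 = c2[b].mm;
                    hits.push_back(h);
                }
        }

        if (hits.empty()) {
            o_mapped[i] = false; o_unique[i] = false; o_comp[i] = NA_INTEGER;
            o_p1[i] = NA_INTEGER; o_p2[i] = NA_INTEGER;
            o_nm1[i] = NA_INTEGER; o_nm2[i] = NA_INTEGER;
            o_nbest[i] = 0; o_ot[i] = NA_LOGICAL;
            continue;
        }
        int best = INT_MAX, n_best = 0, best_idx = -1;
        for (size_t h = 0; h < hits.size(); ++h) {
            int sc = hits[h].mm1 + hits[h].mm2;
            if (sc < best) { best = sc; n_best = 1; best_idx = (int)h; }
            else if (sc == best) ++n_best;
        }
        const PairHit &b = hits[best_idx];
        o_mapped[i] = true;
        o_unique[i] = (n_best == 1);
        o_comp[i] = b.comp + 1;  // 1-based component id for R
        o_p1[i] = b.p1; o_p2[i] = b.p2;
        o_nm1[i] = b.mm1; o_nm2[i] = b.mm2;
        o_nbest[i] = n_best; o_ot[i] = (b.strand == 1);
    }

    return DataFrame::create(
        _["mapped"] = o_mapped, _["unique"] = o_unique, _["ot"] = o_ot,
        _["comp"] = o_comp, _["p1"] = o_p1, _["p2"] = o_p2,
        _["nm1"] = o_nm1, _["nm2"] = o_nm2, _["n_best"] = o_nbest);
}

// Exhaustive single-read oracle: scores every placement on both bisulfite
// strands with reduced-alphabet mismatch counting (mate-1 semantics).
// Independent of the seed table machinery above.
// [[Rcpp::export]]
DataFrame brute_force_cpp(CharacterVector seqs, std::string read) {
    std::vector<int> r_comp, r_pos, r_mm;
    std::vector<std::string> r_strand;
    int best = INT_MAX;
    int len = (int)read.size();
    std::string rd_ct = reduce_ct(read);
    std::string rd_ga = reduce_ga(revcomp(read));
    for (int c = 0; c < seqs.size(); ++c) {
        std::string ref = as<std::string>(seqs[c]);
        std::string ref_ct = reduce_ct(ref), ref_ga = reduce_ga(ref);
        for (int strand = 0; strand < 2; ++strand) {
            const std::string &rd = strand ? rd_ct : rd_ga;
            const std::string &rf = strand ? ref_ct : ref_ga;
            for (int p = 0; p + len <= (int)rf.size(); ++p) {
                int mm = 0;
                for (int j = 0; j < len; ++j)
                    if (rd[j] != rf[p + j]) ++mm;
                if (mm < best) {
                    best = mm;
                    r_comp.clear(); r_pos.clear(); r_mm.clear(); r_strand.clear();
                }
                if (mm == best) {
                    r_comp.push_back(c + 1);
                    r_pos.push_back(p);
                    r_mm.push_back(mm);
                    r_strand.push_back(strand ? "+" : "-");
                }
            }
        }
    }
    return DataFrame::create(
        _["comp"] = IntegerVector(r_comp.begin(), r_comp.end()),
        _["pos"] = IntegerVector(r_pos.begin(), r_pos.end()),
        _["strand"] = CharacterVector(r_strand.begin(), r_strand.end()),
        _["mm"] = IntegerVector(r_mm.begin(), r_mm.end()),
        _["stringsAsFactors"] = false);
}
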