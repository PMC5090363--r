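#ifndef BISULFITR_BSUTIL_H
#define BISULFITR_BSUTIL_H

#include <string>

inline char comp_base(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
    }
}

inline std::string revcomp(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = comp_base(s[i]);
    return out;
}

// three-letter reductions used for bisulfite-aware matching
inline std::string reduce_ct(const std::string &s) {
    std::string out(s);
    for (auto &c : out) if (c == 'C') c = 'T';
    return out;
}

inline std::string reduce_ga(const std::string &s) {
    std::string out(s);
    for (auto &c : out) if (c == 'G') c = 'A';
    return out;
}

inline int base_code(char b) {
    switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

#endif
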