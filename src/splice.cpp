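#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 20 standard proteinogenic amino acids; anything else (B, J, O, U, X, Z, ...)
// is treated as non-standard and excluded from enumeration when requested.
static inline bool is_standard_aa(char c) {
    switch (c) {
    case 'A': case 'C': case 'D': case 'E': case 'F': case 'G': case 'H':
    case 'I': case 'K': case 'L': case 'M': case 'N': case 'P': case 'Q':
    case 'R': case 'S': case 'T': case 'V': case 'W': case 'Y':
        return true;
    default:
        return false;
    }
}

// prefix[i] = number of non-standard residues among the first i characters,
// so a stretch [s, e] (0-based, inclusive) is all-standard iff
// prefix[e + 1] - prefix[s] == 0.
static std::vector<int> nonstandard_prefix(const std::string& seq) {
    std::vector<int> prefix(seq.size() + 1, 0);
    for (size_t i = 0; i < seq.size(); ++i)
        prefix[i + 1] = prefix[i] + (is_standard_aa(seq[i]) ? 0 : 1);
    return prefix;
}

static inline bool clean(const std::vector<int>& pre, int s, int e) {
    // s, e are 1-based inclusive coordinates
    return pre[e] - pre[s - 1] == 0;
}

// Enumerate every cis-splicing scheme of one substrate. Coordinates are
// 1-based inclusive; frag1 is the N-terminal fragment of the *product*.
// In normal order frag1 precedes frag2 in the substrate; in reverse order
// frag2 precedes frag1. Deterministic order: order (normal first), then
// frag1 length, then position, then gap.
// [[Rcpp::export(name = ".cpp_enumerate_cis")]]
DataFrame cpp_enumerate_cis(std::string seq, int k, int max_intervening,
                            int min_gap_normal, int min_gap_reverse,
                            int min_reactant, bool exclude_nonstandard) {
    const int L = (int) seq.size();
    std::vector<int> s1v, e1v, s2v, e2v, gapv;
    std::vector<std::string> orderv, pepv;
    std::vector<int> pre = nonstandard_prefix(seq);

    for (int len1 = min_reactant; len1 <= k - min_reactant; ++len1) {
        const int len2 = k - len1;
        // normal order: frag1 [a, a+len1-1], gap g, frag2 follows
        for (int a = 1; a + len1 - 1 <= L; ++a) {
            const int e1 = a + len1 - 1;
            for (int g = min_gap_normal; g <= max_intervening; ++g) {
                const int s2 = e1 + g + 1, e2 = s2 + len2 - 1;
                if (e2 > L) break;
                if (exclude_nonstandard &&
                    !(clean(pre, a, e1) && clean(pre, s2, e2))) continue;
                s1v.push_back(a); e1v.push_back(e1);
                s2v.push_back(s2); e2v.push_back(e2);
                gapv.push_back(g);
                orderv.push_back("normal");
                pepv.push_back(seq.substr(a - 1, len1) + seq.substr(s2 - 1, len2));
            }
        }
        // reverse order: frag2 [b, b+len2-1] occurs first, frag1 after the gap
        for (int b = 1; b + len2 - 1 <= L; ++b) {
            const int e2 = b + len2 - 1;
            for (int g = min_gap_reverse; g <= max_intervening; ++g) {
                const int s1 = e2 + g + 1, e1 = s1 + len1 - 1;
                if (e1 > L) break;
                if (exclude_nonstandard &&
                    !(clean(pre, b, e2) && clean(pre, s1, e1))) continue;
                s1v.push_back(s1); e1v.push_back(e1);
                s2v.push_back(b); e2v.push_back(e2);
                gapv.push_back(g);
                orderv.push_back("reverse");
                pepv.push_back(seq.substr(s1 - 1, len1) + seq.substr(b - 1, len2));
            }
        }
    }
    return DataFrame::create(
        _["s1"] = s1v, _["e1"] = e1v, _["s2"] = s2v, _["e2"] = e2v,
        _["order"] = orderv, _["intervening"] = gapv, _["peptide"] = pepv,
        _["stringsAsFactors"] = false);
}

// Unique cis-spliced peptides over a set of substrates (memory-light path:
// schemes are streamed into a hash set, one at a time, never materialized).
// [[Rcpp::export(name = ".cpp_cis_unique")]]
CharacterVector cpp_cis_unique(std::vector<std::string> seqs, int k,
                               int max_intervening, int min_gap_normal,
                               int min_gap_reverse, int min_reactant,
                               bool exclude_nonstandard) {
    std::unordered_set<std::string> out;
    for (const std::string& seq : seqs) {
        const int L = (int) seq.size();
        if (L < k) continue;
        std::vector<int> pre = nonstandard_prefix(seq);
        for (int len1 = min_reactant; len1 <= k - min_reactant; ++len1) {
            const int len2 = k - len1;
            for (int a = 1; a + len1 - 1 <= L; ++a) {
                const int e1 = a + len1 - 1;
                const bool ok1 = !exclude_nonstandard || clean(pre, a, e1);
                if (!ok1) continue;
                for (int g = min_gap_normal; g <= max_intervening; ++g) {
                    const int s2 = e1 + g + 1, e2 = s2 + len2 - 1;
                    if (e2 > L) break;
                    if (exclude_nonstandard && !clean(pre, s2, e2)) continue;
                    out.insert(seq.substr(a - 1, len1) + seq.substr(s2 - 1, len2));
                }
            }
            for (int b = 1; b + len2 - 1 <= L; ++b) {
                const int e2 = b + len2 - 1;
                const bool ok2 = !exclude_nonstandard || clean(pre, b, e2);
                if (!ok2) continue;
                for (int g = min_gap_reverse; g <= max_intervening; ++g) {
                    const int s1 = e2 + g + 1, e1 = s1 + len1 - 1;
                    if (e1 > L) break;
                    if (exclude_nonstandard && !clean(pre, s1, e1)) continue;
                    out.insert(seq.substr(s1 - 1, len1) + seq.substr(b - 1, len2));
                }
            }
        }
    }
    std::vector<std::string> v(out.begin(), out.end());
    std::sort(v.begin(), v.end());
    return wrap(v);
}

// Unique non-spliced k-mers over a set of substrates.
// [[Rcpp::export(name = ".cpp_nonspliced_unique")]]
CharacterVector cpp_nonspliced_unique(std::vector<std::string> seqs, int k,
                                      bool exclude_nonstandard) {
    std::unordered_set<std::string> out;
    for (const std::string& seq : seqs) {
        const int L = (int) seq.size();
        if (L < k) continue;
        std::vector<int> pre = nonstandard_prefix(seq);
        for (int s = 1; s + k - 1 <= L; ++s) {
            if (exclude_nonstandard && !clean(pre, s, s + k - 1)) continue;
            out.insert(seq.substr(s - 1, k));
        }
    }
    std::vector<std::string> v(out.begin(), out.end());
    std::sort(v.begin(), v.end());
    return wrap(v);
}
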