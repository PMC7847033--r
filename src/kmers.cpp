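#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

// 2-bit DNA encoding: A=0, C=1, G=2, T=3 (case-insensitive); -1 for
// anything else. The numeric order of codes equals lexicographic order of
// the decoded strings, so sorted codes serialize to byte-sorted k-mer text.
static inline int base2bits(const char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t code, const int k) {
    std::string s((size_t) k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[(size_t) i] = BITS2BASE[code & 3ULL];
        code >>= 2;
    }
    return s;
}

// Encode a k-mer already known to be uppercase ACGT (index serialization).
static inline uint64_t encode_kmer(const char *s, const int k) {
    uint64_t code = 0;
    for (int i = 0; i < k; ++i)
        code = (code << 2) | (uint64_t) base2bits(s[i]);
    return code;
}

// Slide over one sequence emitting the canonical (min of forward and
// reverse-complement) code of every k-mer whose bases are all ACGT.
// Non-ACGT characters reset the window, so such k-mers are skipped.
template <typename Emit>
static void scan_canonical(const char *s, const size_t n, const int k,
                           Emit emit) {
    if (n < (size_t) k) return;
    const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < n; ++i) {
        const int b = base2bits(s[i]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) b) & mask;
        rev = (rev >> 2) | ((uint64_t) (3 - b) << shift);
        if (++run >= k) emit(fwd < rev ? fwd : rev);
    }
}

static void check_k(const int k) {
    if (k < 3 || k > 31) stop("k must be between 3 and 31, got %d", k);
}

// [[Rcpp::export(name = ".kmerSetCpp")]]
CharacterVector kmerSetCpp(const CharacterVector &seqs, const int k) {
    check_k(k);
    std::unordered_set<uint64_t> set;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        if (seqs[j] == NA_STRING) continue;
        const char *s = CHAR(STRING_ELT(seqs, j));
        scan_canonical(s, std::strlen(s), k,
                       [&](uint64_t c) { set.insert(c); });
    }
    std::vector<uint64_t> v(set.begin(), set.end());
    std::sort(v.begin(), v.end());
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = decode_kmer(v[i], k);
    return out;
}

static std::unordered_set<uint64_t> to_set(const CharacterVector &kmers,
                                           const int k) {
    std::unordered_set<uint64_t> set;
    set.reserve((size_t) kmers.size() * 2);
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char *s = CHAR(STRING_ELT(kmers, i));
        if (std::strlen(s) != (size_t) k)
            stop("index k-mer of wrong length: '%s'", s);
        set.insert(encode_kmer(s, k));
    }
    return set;
}

// Per-read evidence counts against the three disjoint index classes.
// Columns: n_graft, n_host, n_shared, n_unknown, n_valid.
// [[Rcpp::export(name = ".profileReadsCpp")]]
IntegerMatrix profileReadsCpp(const CharacterVector &reads,
                              const CharacterVector &graftOnly,
                              const CharacterVector &hostOnly,
                              const CharacterVector &shared,
                              const int k) {
    check_k(k);
    const std::unordered_set<uint64_t> g = to_set(graftOnly, k);
    const std::unordered_set<uint64_t> h = to_set(hostOnly, k);
    const std::unordered_set<uint64_t> s = to_set(shared, k);

    const R_xlen_t n = reads.size();
    IntegerMatrix out(n, 5);
    for (R_xlen_t i = 0; i < n; ++i) {
        int ng = 0, nh = 0, ns = 0, nu = 0;
        if (reads[i] != NA_STRING) {
            const char *seq = CHAR(STRING_ELT(reads, i));
            scan_canonical(seq, std::strlen(seq), k, [&](uint64_t c) {
                if (g.count(c)) ++ng;
                else if (h.count(c)) ++nh;
                else if (s.count(c)) ++ns;
                else ++nu;
            });
        }
        out(i, 0) = ng; out(i, 1) = nh; out(i, 2) = ns; out(i, 3) = nu;
        out(i, 4) = ng + nh + ns + nu;
    }
    colnames(out) = CharacterVector::create("n_graft", "n_host", "n_shared",
                                            "n_unknown", "n_valid");
    return out;
}
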