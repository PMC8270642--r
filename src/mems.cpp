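#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit codes for A,C,G,T; 4 = ambiguous (never matches, not even itself,
// mirroring MUMmer's -n flag: only a,c,g,t participate in matches).
static inline std::vector<uint8_t> encode(const std::string& s) {
    std::vector<uint8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': v[i] = 0; break;
        case 'C': v[i] = 1; break;
        case 'G': v[i] = 2; break;
        case 'T': v[i] = 3; break;
        default:  v[i] = 4; break;
        }
    }
    return v;
}

// All maximal exact matches of length >= min_length between the forward
// strands of ref and qry, by k-mer seeding (k = min(31, min_length)) with
// leftmost-seed deduplication and maximal bidirectional extension. Each
// maximal match contains a seed whose start coincides with the match start
// on its diagonal, so processing only seeds that cannot be extended one
// base to the left reports every maximal match exactly once.
// [[Rcpp::export]]
DataFrame cpp_find_mems(std::string ref, std::string qry, int min_length) {
    if (min_length < 1) stop("min_length must be >= 1");
    const std::vector<uint8_t> r = encode(ref), q = encode(qry);
    const int n = (int)r.size(), m = (int)q.size();
    const int k = min_length < 31 ? min_length : 31;

    std::vector<int> ref_start, qry_start, len;
    if (n >= k && m >= k) {
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        // hash all clean (ACGT-only) ref k-mers
        std::unordered_multimap<uint64_t, int> index;
        index.reserve((size_t)n);
        {
            uint64_t h = 0; int run = 0;
            for (int i = 0; i < n; ++i) {
                if (r[i] < 4) { h = ((h << 2) | r[i]) & mask; ++run; }
                else { run = 0; h = 0; }
                if (run >= k) index.emplace(h, i - k + 1);
            }
        }
        uint64_t h = 0; int run = 0;
        for (int j = 0; j < m; ++j) {
            if (q[j] < 4) { h = ((h << 2) | q[j]) & mask; ++run; }
            else { run = 0; h = 0; }
            if (run < k) continue;
            const int js = j - k + 1; // seed start in qry
            auto range = index.equal_range(h);
            for (auto it = range.first; it != range.second; ++it) {
                const int is = it->second;
                // leftmost seed of its match on this diagonal?
                if (is > 0 && js > 0 && r[is - 1] < 4 &&
                    r[is - 1] == q[js - 1]) continue;
                // extend right maximally
                int e = k;
                while (is + e < n && js + e < m && r[is + e] < 4 &&
                       r[is + e] == q[js + e]) ++e;
                if (e >= min_length) {
                    ref_start.push_back(is + 1);
                    qry_start.push_back(js + 1);
                    len.push_back(e);
                }
            }
        }
    }
    return DataFrame::create(_["ref_start"] = ref_start,
                             _["qry_start"] = qry_start,
                             _["length"] = len);
}
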