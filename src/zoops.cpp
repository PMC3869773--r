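#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Exhaustive k-mer ZOOPS counting with a Hamming-mismatch neighbourhood.
// Sequences are 2-bit encoded (k <= 14 fits a 32-bit code); windows
// containing a non-ACGT base are skipped.  For every k-mer present in
// the target sequences we count the target and background sequences that
// contain the k-mer or any word within max_mm mismatches of it
// (zero-or-one occurrence per sequence).

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint32_t, std::vector<int> > PostingsMap;

// collect the sorted-unique k-mer codes of each sequence into `postings`
// (code -> list of sequence indices, each index at most once per code)
static void index_sequences(const CharacterVector &seqs, int k,
                            PostingsMap &postings) {
  for (int s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    int L = (int)str.size();
    if (L < k) continue;
    std::vector<uint32_t> codes;
    uint32_t code = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int valid = 0;  // length of the current run of ACGT bases
    for (int i = 0; i < L; ++i) {
      int b = base_code(str[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++valid >= k) codes.push_back(code);
    }
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    for (size_t i = 0; i < codes.size(); ++i)
      postings[codes[i]].push_back(s);
  }
}

static std::string decode(uint32_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bases[code & 3u]; code >>= 2; }
  return s;
}

// distinct codes within Hamming distance <= max_mm of `code`
static void neighbourhood(uint32_t code, int k, int max_mm,
                          std::vector<uint32_t> &out) {
  out.clear();
  out.push_back(code);
  if (max_mm >= 1) {
    for (int p = 0; p < k; ++p) {
      uint32_t shift = 2u * (uint32_t)(k - 1 - p);
      uint32_t cur = (code >> shift) & 3u;
      for (uint32_t b = 0; b < 4; ++b) {
        if (b == cur) continue;
        uint32_t nb = (code & ~(3u << shift)) | (b << shift);
        out.push_back(nb);
        if (max_mm >= 2) {
          for (int p2 = p + 1; p2 < k; ++p2) {
            uint32_t shift2 = 2u * (uint32_t)(k - 1 - p2);
            uint32_t cur2 = (nb >> shift2) & 3u;
            for (uint32_t b2 = 0; b2 < 4; ++b2) {
              if (b2 == cur2) continue;
              out.push_back((nb & ~(3u << shift2)) | (b2 << shift2));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame kmer_zoops_counts(CharacterVector target_seqs,
                            CharacterVector background_seqs,
                            int k, int max_mm) {
  if (k < 1 || k > 14) stop("k must be in 1..14");
  if (max_mm < 0 || max_mm > 2) stop("max_mm must be 0, 1 or 2");

  PostingsMap post_t, post_b;
  index_sequences(target_seqs, k, post_t);
  index_sequences(background_seqs, k, post_b);

  std::vector<uint32_t> candidates;
  candidates.reserve(post_t.size());
  for (PostingsMap::const_iterator it = post_t.begin(); it != post_t.end(); ++it)
    candidates.push_back(it->first);
  std::sort(candidates.begin(), candidates.end());

  int nt = target_seqs.size(), nb = background_seqs.size();
  std::vector<int> stamp_t(nt, -1), stamp_b(nb, -1);
  std::vector<uint32_t> nbrs;

  int nc = (int)candidates.size();
  CharacterVector kmer_out(nc);
  IntegerVector kt_out(nc), kb_out(nc), kt_exact_out(nc);

  for (int ci = 0; ci < nc; ++ci) {
    uint32_t c = candidates[ci];
    neighbourhood(c, k, max_mm, nbrs);
    int kt = 0, kb = 0;
    for (size_t ni = 0; ni < nbrs.size(); ++ni) {
      PostingsMap::const_iterator it = post_t.find(nbrs[ni]);
      if (it != post_t.end())
        for (size_t j = 0; j < it->second.size(); ++j) {
          int s = it->second[j];
          if (stamp_t[s] != ci) { stamp_t[s] = ci; ++kt; }
        }
      it = post_b.find(nbrs[ni]);
      if (it != post_b.end())
        for (size_t j = 0; j < it->second.size(); ++j) {
          int s = it->second[j];
          if (stamp_b[s] != ci) { stamp_b[s] = ci; ++kb; }
        }
    }
    kmer_out[ci] = decode(c, k);
    kt_out[ci] = kt;
    kb_out[ci] = kb;
    // ZOOPS count at zero mismatches: the candidate's own postings list
    kt_exact_out[ci] = (int)post_t.find(c)->second.size();
  }
  return DataFrame::create(_["kmer"] = kmer_out,
                           _["k_target"] = kt_out,
                           _["k_background"] = kb_out,
                           _["k_target_exact"] = kt_exact_out,
                           _["stringsAsFactors"] = false);
}
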