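// 2-bit k-mer kernel: encoding, canonicalization, extraction, counting.
// A=0, C=1, G=2, T=3; most-significant bits hold the 5' end, so numeric
// order on codes equals lexicographic order on the k-mer strings.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t kmask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static void check_k(int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32, got %d", k);
}

static uint64_t encode_one(const std::string& s, int k) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0)
      stop("invalid base '%c' in k-mer '%s' (A/C/G/T only)", s[i], s.c_str());
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

static std::string decode_one(uint64_t code, int k) {
  static const char* bases = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    check_k(k);
    out[i] = decode_one(revcomp_code(encode_one(s, k), k), k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    check_k(k);
    uint64_t f = encode_one(s, k);
    uint64_t r = revcomp_code(f, k);
    out[i] = decode_one(std::min(f, r), k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_encode(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    int k = (int)s.size();
    check_k(k);
    out[i] = std::to_string(encode_one(s, k));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(CharacterVector codes, int k) {
  check_k(k);
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string c = as<std::string>(codes[i]);
    uint64_t v = 0;
    for (size_t j = 0; j < c.size(); ++j) {
      if (c[j] < '0' || c[j] > '9')
        stop("k-mer code '%s' is not a decimal integer", c.c_str());
      v = v * 10ULL + (uint64_t)(c[j] - '0');
    }
    out[i] = decode_one(v, k);
  }
  return out;
}

// Rolling extraction of canonical k-mers from one sequence.
// Windows containing any non-ACGT character are skipped entirely.
// [[Rcpp::export]]
List cpp_extract(std::string seq, int k) {
  check_k(k);
  int n = (int)seq.size();
  std::vector<int> pos;
  std::vector<uint64_t> codes;
  uint64_t mask = kmask(k);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // length of current valid-base run
  int shift = 2 * (k - 1);
  for (int i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((3ULL - (uint64_t)b) << shift);
    if (++run >= k) {
      pos.push_back(i - k + 2);  // 1-based window start
      codes.push_back(std::min(fwd, rev));
    }
  }
  int m = (int)codes.size();
  CharacterVector km(m);
  for (int i = 0; i < m; ++i) km[i] = decode_one(codes[i], k);
  return List::create(_["pos"] = wrap(pos), _["kmer"] = km);
}

// Sorted unique canonical k-mers over a collection of sequences.
// [[Rcpp::export]]
CharacterVector cpp_unique_kmers(CharacterVector seqs, int k) {
  check_k(k);
  std::vector<uint64_t> codes;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    if (CharacterVector::is_na(seqs[s])) continue;
    std::string seq = as<std::string>(seqs[s]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((3ULL - (uint64_t)b) << shift);
      if (++run >= k) codes.push_back(std::min(fwd, rev));
    }
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  int m = (int)codes.size();
  CharacterVector out(m);
  for (int i = 0; i < m; ++i) out[i] = decode_one(codes[i], k);
  return out;
}

// Occurrence counts of panel k-mers over a sequence collection.
// Panel entries are canonicalized before lookup; every overlapping
// window is counted; returns counts aligned to the panel plus the
// number of scanned bases.
// [[Rcpp::export]]
List cpp_count(CharacterVector panel, CharacterVector seqs, int k) {
  check_k(k);
  int np = panel.size();
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(np * 2);
  for (int i = 0; i < np; ++i) {
    std::string s = as<std::string>(panel[i]);
    if ((int)s.size() != k)
      stop("panel k-mer '%s' does not have length k=%d", s.c_str(), k);
    uint64_t f = encode_one(s, k);
    idx[std::min(f, revcomp_code(f, k))] = i;
  }
  IntegerVector counts(np);
  double bases = 0;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    if (CharacterVector::is_na(seqs[s])) continue;
    std::string seq = as<std::string>(seqs[s]);
    bases += (double)seq.size();
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((3ULL - (uint64_t)b) << shift);
      if (++run >= k) {
        std::unordered_map<uint64_t, int>::iterator it =
          idx.find(std::min(fwd, rev));
        if (it != idx.end()) counts[it->second]++;
      }
    }
  }
  return List::create(_["count"] = counts, _["bases_scanned"] = bases);
}

// 3'-end quality trimming: kept length = position of the last base whose
// Phred+33 score reaches the threshold (fastq_quality_trimmer -t rule).
// [[Rcpp::export]]
IntegerVector cpp_trim_length(CharacterVector quals, int threshold) {
  int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int keep = 0;
    for (int j = (int)q.size() - 1; j >= 0; --j) {
      int score = (int)q[j] - 33;
      if (score < 0 || score > 93)
        stop("quality character '%c' outside Phred+33 range", q[j]);
      if (score >= threshold) { keep = j + 1; break; }
    }
    // validate the retained prefix too
    for (int j = 0; j < keep; ++j) {
      int score = (int)q[j] - 33;
      if (score < 0 || score > 93)
        stop("quality character '%c' outside Phred+33 range", q[j]);
    }
    out[i] = keep;
  }
  return out;
}
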