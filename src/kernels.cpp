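#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <deque>
#include <set>
using namespace Rcpp;

// 53-bit mask: hash values must be exactly representable as doubles on the R side.
static const uint64_t MASK53 = (1ULL << 53) - 1;

// Fixed splitmix64-style finalizer. Constants are committed here so that
// sketches are reproducible across platforms and R sessions.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or other ambiguity code
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string unpack_kmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[v & 3ULL];
    v >>= 2;
  }
  return s;
}

// Rolling 2-bit packing of all k-mers of seq. valid[i] == false where the
// window [i, i+k) contains a non-ACGT character. fwd/rc are the packed
// forward and reverse-complement encodings.
static void pack_all(const std::string& seq, int k,
                     std::vector<uint64_t>& fwd, std::vector<uint64_t>& rc,
                     std::vector<char>& valid) {
  const size_t L = seq.size();
  const size_t n = (L >= (size_t)k) ? L - k + 1 : 0;
  fwd.assign(n, 0); rc.assign(n, 0); valid.assign(n, 0);
  if (n == 0) return;
  const uint64_t maskk = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t f = 0, r = 0;
  int run = 0; // length of current run of valid bases
  for (size_t i = 0; i < L; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) {
      run = 0; f = 0; r = 0;
    } else {
      ++run;
      f = ((f << 2) | (uint64_t)b) & maskk;
      r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    }
    if (i + 1 >= (size_t)k) {
      size_t pos = i + 1 - k;
      if (run >= k) { fwd[pos] = f; rc[pos] = r; valid[pos] = 1; }
    }
  }
}

// Minimizer extraction under the standard (w,k) scheme: for every window of w
// consecutive k-mers emit the minimum under the ordering; the result is the
// deduplicated set of chosen k-mers, returned as strings.
// ordering: 0 = hash (mix64 of packed value), 1 = lexicographic (packed value).
// canonical: compare each k-mer with its reverse complement under the same
// ordering and keep the smaller form.
// [[Rcpp::export]]
CharacterVector cpp_minimizers(std::string seq, int k, int w,
                               int ordering, bool canonical) {
  std::vector<uint64_t> fwd, rc; std::vector<char> valid;
  pack_all(seq, k, fwd, rc, valid);
  const size_t n = fwd.size();
  std::vector<uint64_t> code(n), key(n);
  for (size_t i = 0; i < n; ++i) {
    if (!valid[i]) { key[i] = ~0ULL; code[i] = 0; continue; }
    uint64_t cf = fwd[i], cr = rc[i];
    uint64_t kf = (ordering == 0) ? mix64(cf) : cf;
    uint64_t kr = (ordering == 0) ? mix64(cr) : cr;
    if (canonical && kr < kf) { code[i] = cr; key[i] = kr; }
    else { code[i] = cf; key[i] = kf; }
  }
  std::set<uint64_t> chosen;
  if (n >= (size_t)w) {
    // sliding-window minimum over key[] with a monotone deque of indices
    std::deque<size_t> dq;
    for (size_t i = 0; i < n; ++i) {
      while (!dq.empty() && key[dq.back()] >= key[i]) dq.pop_back();
      dq.push_back(i);
      if (i + 1 >= (size_t)w) {
        size_t lo = i + 1 - w;
        while (dq.front() < lo) dq.pop_front();
        if (valid[dq.front()]) chosen.insert(code[dq.front()]);
      }
    }
  }
  CharacterVector out(chosen.size());
  size_t j = 0;
  for (uint64_t v : chosen) out[j++] = unpack_kmer(v, k);
  return out;
}

// Minhash sketch over T random trials: sketch[t] = min over k-mers m of
// H(m, salt ^ t), with H(m, s) = mix64(pack(m) ^ mix64(s)). Values are
// masked to 53 bits so the R side can compare them exactly as doubles.
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector kmers, int trials, double salt) {
  const int n = kmers.size();
  if (n == 0) stop("cannot sketch an empty k-mer set");
  std::vector<uint64_t> packed(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t v = 0;
    for (char c : s) {
      int b = base2bit(c);
      if (b < 0) stop("k-mer contains a non-ACGT character");
      v = (v << 2) | (uint64_t)b;
    }
    packed[i] = v;
  }
  NumericVector out(trials);
  uint64_t s64 = (uint64_t)(int64_t)salt;
  for (int t = 0; t < trials; ++t) {
    uint64_t seed = mix64(s64 ^ (uint64_t)t);
    uint64_t best = ~0ULL;
    for (int i = 0; i < n; ++i) {
      // mask before the min so the sketch is the true minimum of the
      // 53-bit hash values reported to R
      uint64_t h = mix64(packed[i] ^ seed) & MASK53;
      if (h < best) best = h;
    }
    out[t] = (double)best;
  }
  return out;
}

// Per-position packed forward k-mer codes (exact in doubles for k <= 26);
// NA where the k-mer window contains a non-ACGT base. Used for anchor seeding.
// [[Rcpp::export]]
NumericVector cpp_kmer_codes(std::string seq, int k) {
  if (k > 26) stop("k must be <= 26 for exact double representation");
  std::vector<uint64_t> fwd, rc; std::vector<char> valid;
  pack_all(seq, k, fwd, rc, valid);
  NumericVector out(fwd.size());
  for (size_t i = 0; i < fwd.size(); ++i)
    out[i] = valid[i] ? (double)fwd[i] : NA_REAL;
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
        case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
        case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
        case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
        default:  r[j] = c;
      }
    }
    out[i] = r;
  }
  return out;
}
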