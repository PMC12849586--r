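// Exact canonical k-mer counting over DNA sequences.
//
// k up to 63 is packed 2 bits/base into an unsigned 128-bit integer; the
// numeric order of the packed forward code equals lexicographic order over
// {A,C,G,T}, so canonical = min(code, revcomp code) matches the usual
// string definition. Windows containing any non-ACGT base are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x;
    uint64_t hi = (uint64_t)(x >> 64);
    return (size_t)(splitmix64(lo) ^ splitmix64(hi + 0x632be59bd9b4e019ULL));
  }
};

typedef std::unordered_map<u128, uint64_t, U128Hash> kmap;

struct KmerTable {
  int k;
  double mass;   // total valid (N-free) windows counted across all input
  kmap tab;
  KmerTable(int k_) : k(k_), mass(0.0) {}
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate canonical codes of all valid windows of seq, calling f(code).
template <typename F>
static void for_each_canonical(const std::string &seq, int k, F f) {
  const int L = (int)seq.size();
  if (L < k) return;
  const u128 mask = (k == 64) ? ~(u128)0 : (((u128)1 << (2 * k)) - 1);
  u128 fwd = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (int i = 0; i < L; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)c) & mask;
    rc = (rc >> 2) | ((u128)(3 - c) << shift);
    if (++run >= k) f(fwd < rc ? fwd : rc);
  }
}

static std::string decode_kmer(u128 code, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = 0; i < k; ++i)
    s[i] = B[(int)((code >> (2 * (k - 1 - i))) & 3)];
  return s;
}

// Encode a k-mer string; returns false on any non-ACGT character.
static bool encode_kmer(const std::string &s, int k, u128 &fwd, u128 &rc) {
  if ((int)s.size() != k) return false;
  fwd = 0; rc = 0;
  const int shift = 2 * (k - 1);
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (u128)c;
    rc = (rc >> 2) | ((u128)(3 - c) << shift);
  }
  return true;
}

// [[Rcpp::export]]
SEXP kt_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 63) stop("k must be in [1, 63]");
  KmerTable *kt = new KmerTable(k);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    for_each_canonical(seq, k, [&](u128 code) {
      ++kt->tab[code];
      kt->mass += 1.0;
    });
  }
  XPtr<KmerTable> p(kt, true);
  return p;
}

// [[Rcpp::export]]
double kt_size(SEXP ptr) {
  XPtr<KmerTable> p(ptr);
  return (double)p->tab.size();
}

// [[Rcpp::export]]
double kt_mass(SEXP ptr) {
  XPtr<KmerTable> p(ptr);
  return p->mass;
}

// [[Rcpp::export]]
int kt_k(SEXP ptr) {
  XPtr<KmerTable> p(ptr);
  return p->k;
}

// Counts for given k-mer strings (canonicalized before lookup); 0 if absent.
// [[Rcpp::export]]
NumericVector kt_lookup(SEXP ptr, CharacterVector kmers) {
  XPtr<KmerTable> p(ptr);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    u128 fwd, rc;
    std::string s = as<std::string>(kmers[i]);
    if (!encode_kmer(s, p->k, fwd, rc))
      stop("invalid k-mer '%s' (length or alphabet)", s.c_str());
    u128 canon = fwd < rc ? fwd : rc;
    kmap::const_iterator it = p->tab.find(canon);
    out[i] = (it == p->tab.end()) ? 0.0 : (double)it->second;
  }
  return out;
}

// Full table as (kmer, count); intended for small indexes (tests, fixtures).
// [[Rcpp::export]]
List kt_entries(SEXP ptr) {
  XPtr<KmerTable> p(ptr);
  size_t n = p->tab.size();
  if (n > 5000000) stop("k-mer table too large to materialize (%d entries)", (int)n);
  CharacterVector km(n);
  NumericVector ct(n);
  size_t i = 0;
  for (kmap::const_iterator it = p->tab.begin(); it != p->tab.end(); ++it, ++i) {
    km[i] = decode_kmer(it->first, p->k);
    ct[i] = (double)it->second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// Canonical k-mer of every window of seq (NA where the window contains a
// non-ACGT base). Used by the repeat scanner and as a cross-check surface.
// [[Rcpp::export]]
CharacterVector seq_canonical_windows(std::string seq, int k) {
  if (k < 1 || k > 63) stop("k must be in [1, 63]");
  int L = (int)seq.size();
  int n = L - k + 1;
  if (n < 1) return CharacterVector(0);
  CharacterVector out(n, NA_STRING);
  const u128 mask = (((u128)1 << (2 * k)) - 1);
  u128 fwd = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (int i = 0; i < L; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)c) & mask;
    rc = (rc >> 2) | ((u128)(3 - c) << shift);
    if (++run >= k) {
      u128 canon = fwd < rc ? fwd : rc;
      out[i - k + 1] = decode_kmer(canon, k);
    }
  }
  return out;
}

// Distinct canonical k-mers of a contig whose count in the reference index is
// <= max_ref_copy. check_present: error if any contig k-mer is absent from the
// reference (the contig was not part of the assembly the index was built on).
// [[Rcpp::export]]
CharacterVector contig_diagnostic(std::string seq, SEXP ref_ptr, int max_ref_copy,
                                  bool check_present) {
  XPtr<KmerTable> ref(ref_ptr);
  const int k = ref->k;
  std::unordered_set<u128, U128Hash> seen;
  std::vector<u128> diag;
  bool absent = false;
  for_each_canonical(seq, k, [&](u128 code) {
    if (!seen.insert(code).second) return;
    kmap::const_iterator it = ref->tab.find(code);
    uint64_t rc = (it == ref->tab.end()) ? 0 : it->second;
    if (rc == 0) absent = true;
    if (rc >= 1 && rc <= (uint64_t)max_ref_copy) diag.push_back(code);
  });
  if (check_present && absent)
    stop("contig contains k-mers absent from the reference index; was it part of the assembly?");
  CharacterVector out(diag.size());
  for (size_t i = 0; i < diag.size(); ++i) out[i] = decode_kmer(diag[i], k);
  return out;
}

// Fused per-contig scoring used by classify_assembly(): diagnostic-set size and
// summed +B/0B read counts over the diagnostic set, in one pass.
// [[Rcpp::export]]
NumericVector contig_diag_score(std::string seq, SEXP ref_ptr, SEXP plus_ptr,
                                SEXP zero_ptr, int max_ref_copy, bool check_present) {
  XPtr<KmerTable> ref(ref_ptr);
  XPtr<KmerTable> plus(plus_ptr);
  XPtr<KmerTable> zero(zero_ptr);
  if (plus->k != ref->k || zero->k != ref->k)
    stop("all k-mer indexes must share the same k");
  std::unordered_set<u128, U128Hash> seen;
  double n_diag = 0.0, c_plus = 0.0, c_zero = 0.0;
  bool absent = false;
  for_each_canonical(seq, ref->k, [&](u128 code) {
    if (!seen.insert(code).second) return;
    kmap::const_iterator it = ref->tab.find(code);
    uint64_t rc = (it == ref->tab.end()) ? 0 : it->second;
    if (rc == 0) { absent = true; return; }
    if (rc > (uint64_t)max_ref_copy) return;
    n_diag += 1.0;
    kmap::const_iterator ip = plus->tab.find(code);
    if (ip != plus->tab.end()) c_plus += (double)ip->second;
    kmap::const_iterator iz = zero->tab.find(code);
    if (iz != zero->tab.end()) c_zero += (double)iz->second;
  });
  if (check_present && absent)
    stop("contig contains k-mers absent from the reference index; was it part of the assembly?");
  return NumericVector::create(_["n_diag"] = n_diag, _["c_plus"] = c_plus,
                               _["c_zero"] = c_zero);
}
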