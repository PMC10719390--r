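// Core k-mer kernels: canonical counting, membership scans, MinHash
// sketching, unique-anchor reference index and read placement, naive pileup.
// K-mers are 2-bit packed into 64-bit codes (k <= 31), canonical = min of a
// k-mer code and its reverse-complement code; lexicographic order on ACGT
// strings coincides with numeric order on codes.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string code2kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Calls f(pos, canonical_code, forward_is_canonical) for every k-window of s
// made only of ACGT bases; windows touching any other character are skipped.
template <typename F>
static void for_each_canonical(const char* s, size_t n, int k, F&& f) {
  if (n < (size_t)k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << shift);
    if (++valid >= k) {
      bool fwd_canon = fwd <= rev;
      f(i + 1 - (size_t)k, fwd_canon ? fwd : rev, fwd_canon);
    }
  }
}

// Parse an ACGT string of length k into its canonical code; returns false on
// any other character or length mismatch.
static bool parse_canonical(const char* s, size_t n, int k, uint64_t* out) {
  if (n != (size_t)k) return false;
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  uint64_t rc = revcomp_code(code, k);
  *out = code <= rc ? code : rc;
  return true;
}

static std::unordered_set<uint64_t> kmer_set_from_strings(
    const CharacterVector& kmers, int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2 + 16);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t code;
    if (!parse_canonical(s, strlen(s), k, &code))
      stop("invalid k-mer string at position %d (expected %d ACGT bases)",
           (int)(i + 1), k);
    set.insert(code);
  }
  return set;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, double> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for_each_canonical(s, strlen(s), k,
                       [&](size_t, uint64_t code, bool) { counts[code] += 1.0; });
  }
  std::vector<std::pair<uint64_t, double>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  CharacterVector kmer(v.size());
  NumericVector count(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    kmer[i] = code2kmer(v[i].first, k);
    count[i] = v[i].second;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Positional hit count per read: number of k-windows whose canonical k-mer is
// in `kmers` (a k-mer occurring twice counts twice). `distinct` counts each
// distinct matching k-mer once instead.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hits(CharacterVector reads, CharacterVector kmers,
                            int k, bool distinct = false) {
  std::unordered_set<uint64_t> set = kmer_set_from_strings(kmers, k);
  IntegerVector hits(reads.size());
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = 0;
    if (distinct) seen.clear();
    for_each_canonical(s, strlen(s), k, [&](size_t, uint64_t code, bool) {
      if (set.count(code)) {
        if (distinct) {
          if (seen.insert(code).second) ++n;
        } else {
          ++n;
        }
      }
    });
    hits[i] = n;
  }
  return hits;
}

// Windowed membership counts for painting: for each sequence, the number of
// k-mer start positions per `window` bp whose canonical k-mer is in `kmers`.
// [[Rcpp::export]]
List cpp_window_hits(CharacterVector seqs, CharacterVector kmers, int k,
                     int window) {
  std::unordered_set<uint64_t> set = kmer_set_from_strings(kmers, k);
  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(s);
    size_t nwin = n == 0 ? 0 : (n + window - 1) / window;
    IntegerVector w((R_xlen_t)nwin);
    for_each_canonical(s, n, k, [&](size_t pos, uint64_t code, bool) {
      if (set.count(code)) w[pos / window] += 1;
    });
    out[i] = w;
  }
  return out;
}

// Totals for the k-mer QV estimator: number of valid k-mer positions and the
// number of those positions present in the read k-mer set (by multiplicity or
// by distinct k-mer).
// [[Rcpp::export]]
NumericVector cpp_presence_stats(CharacterVector seqs, CharacterVector kmers,
                                 int k, bool distinct = false) {
  std::unordered_set<uint64_t> set = kmer_set_from_strings(kmers, k);
  double total = 0, present = 0;
  std::unordered_set<uint64_t> seen_total, seen_present;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for_each_canonical(s, strlen(s), k, [&](size_t, uint64_t code, bool) {
      if (distinct) {
        if (seen_total.insert(code).second) ++total;
        if (set.count(code) && seen_present.insert(code).second) ++present;
      } else {
        ++total;
        if (set.count(code)) ++present;
      }
    });
  }
  return NumericVector::create(total, present);
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Bottom-s MinHash sketch over distinct canonical k-mers. Hashes are
// splitmix64 values masked to 53 bits so they round-trip exactly through R
// doubles; returned sorted ascending.
// [[Rcpp::export]]
NumericVector cpp_minhash_sketch(CharacterVector seqs, int k, int sketch_size) {
  const uint64_t mask53 = (1ULL << 53) - 1;
  std::unordered_set<uint64_t> hashes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for_each_canonical(s, strlen(s), k, [&](size_t, uint64_t code, bool) {
      hashes.insert(splitmix64(code) & mask53);
    });
  }
  std::vector<uint64_t> v(hashes.begin(), hashes.end());
  size_t s = std::min((size_t)sketch_size, v.size());
  std::partial_sort(v.begin(), v.begin() + s, v.end());
  NumericVector out(s);
  for (size_t i = 0; i < s; ++i) out[i] = (double)v[i];
  return out;
}

// ---- unique-anchor reference index ------------------------------------

struct RefIndex {
  int k;
  std::vector<int> chrom_len;
  // canonical code -> packed (chrom << 33) | (pos << 1) | fwd_is_canonical
  std::unordered_map<uint64_t, uint64_t> pos;
  uint64_t n_positions;  // total valid k-mer positions scanned
};

static const uint64_t DUP = ~0ULL;

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  RefIndex* idx = new RefIndex();
  idx->k = k;
  idx->n_positions = 0;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    const char* s = CHAR(STRING_ELT(seqs, c));
    size_t n = strlen(s);
    idx->chrom_len.push_back((int)n);
    for_each_canonical(s, n, k, [&](size_t pos, uint64_t code, bool fwd) {
      ++idx->n_positions;
      auto it = idx->pos.find(code);
      if (it == idx->pos.end()) {
        idx->pos[code] =
            ((uint64_t)c << 33) | ((uint64_t)pos << 1) | (fwd ? 1ULL : 0ULL);
      } else {
        it->second = DUP;
      }
    });
  }
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  uint64_t uniq = 0;
  for (auto& kv : idx->pos)
    if (kv.second != DUP) ++uniq;
  return List::create(_["k"] = idx->k, _["n_unique"] = (double)uniq,
                      _["n_positions"] = (double)idx->n_positions,
                      _["chrom_len"] = wrap(idx->chrom_len));
}

// Place reads by unique-anchor voting. Each anchor k-mer that is unique in
// the reference votes for an implied (chrom, read start, strand); the
// placement is the plurality vote if it has >= min_anchors supporting anchors
// and > 50% of the anchor votes, else the read is unplaced.
// Returns chrom (1-based, NA if unplaced), start (0-based), strand (+1/-1),
// n_anchors (votes for winner), n_votes (total anchor votes).
// [[Rcpp::export]]
List cpp_place_reads(SEXP xp, CharacterVector reads, int min_anchors) {
  XPtr<RefIndex> idx(xp);
  const int k = idx->k;
  R_xlen_t n = reads.size();
  IntegerVector chrom(n, NA_INTEGER), start(n, NA_INTEGER),
      strand(n, NA_INTEGER), n_anchor(n, 0), n_votes(n, 0);
  std::unordered_map<uint64_t, int> votes;
  const int64_t OFF = 1LL << 20;  // implied starts can be slightly negative
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    size_t len = strlen(s);
    if (len < (size_t)k) continue;
    votes.clear();
    int total = 0;
    for_each_canonical(s, len, k, [&](size_t pos, uint64_t code, bool read_fwd) {
      auto it = idx->pos.find(code);
      if (it == idx->pos.end() || it->second == DUP) return;
      uint64_t packed = it->second;
      int c = (int)(packed >> 33);
      int64_t rpos = (int64_t)((packed >> 1) & ((1ULL << 32) - 1));
      bool ref_fwd = packed & 1ULL;
      bool plus = (read_fwd == ref_fwd);
      int64_t st = plus ? rpos - (int64_t)pos
                        : rpos - (int64_t)(len - (size_t)k - pos);
      uint64_t key = ((uint64_t)c << 41) | ((uint64_t)(st + OFF) << 1) |
                     (plus ? 1ULL : 0ULL);
      votes[key] += 1;
      ++total;
    });
    if (total == 0) continue;
    uint64_t best_key = 0;
    int best = 0;
    for (auto& kv : votes) {
      if (kv.second > best) { best = kv.second; best_key = kv.first; }
    }
    n_votes[i] = total;
    if (best >= min_anchors && 2 * best > total) {
      chrom[i] = (int)(best_key >> 41) + 1;
      start[i] = (int)((int64_t)((best_key >> 1) & ((1ULL << 40) - 1)) - OFF);
      strand[i] = (best_key & 1ULL) ? 1 : -1;
      n_anchor[i] = best;
    }
  }
  return List::create(_["chrom"] = chrom, _["start"] = start,
                      _["strand"] = strand, _["n_anchors"] = n_anchor,
                      _["n_votes"] = n_votes);
}

// Naive pileup over placed substitution-only reads of one sample.
// strand: +1 read aligns forward, -1 read bases are the reverse complement of
// the reference span. Returns per-chromosome heterozygous-column counts plus
// per-chromosome column depth tallies used for coverage summaries.
// [[Rcpp::export]]
List cpp_pileup_het(IntegerVector chrom, IntegerVector start,
                    IntegerVector strand, CharacterVector reads,
                    IntegerVector chrom_len, int min_depth,
                    double min_allele_frac) {
  int nchrom = chrom_len.size();
  IntegerVector n_het(nchrom, 0);
  NumericVector bases_covered(nchrom, 0.0);  // columns with depth >= min_depth
  for (int c = 0; c < nchrom; ++c) {
    int L = chrom_len[c];
    std::vector<uint32_t> cnt((size_t)L * 4, 0);
    bool any = false;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
      if (chrom[i] == NA_INTEGER || chrom[i] != c + 1) continue;
      const char* s = CHAR(STRING_ELT(reads, i));
      int len = (int)strlen(s);
      int st = start[i];
      bool plus = strand[i] >= 0;
      for (int j = 0; j < len; ++j) {
        int b = base2bits(s[j]);
        if (b < 0) continue;
        int p = plus ? st + j : st + (len - 1 - j);
        if (p < 0 || p >= L) continue;
        int bb = plus ? b : 3 - b;
        cnt[(size_t)p * 4 + bb] += 1;
        any = true;
      }
    }
    if (!any) continue;
    for (int p = 0; p < L; ++p) {
      uint32_t* q = &cnt[(size_t)p * 4];
      uint32_t depth = q[0] + q[1] + q[2] + q[3];
      if (depth < (uint32_t)min_depth) continue;
      bases_covered[c] += 1;
      uint32_t m1 = 0, m2 = 0;
      for (int b = 0; b < 4; ++b) {
        if (q[b] >= m1) { m2 = m1; m1 = q[b]; }
        else if (q[b] > m2) m2 = q[b];
      }
      double f2 = (double)m2 / depth;
      if (f2 >= min_allele_frac && f2 <= 1.0 - min_allele_frac) n_het[c] += 1;
    }
  }
  return List::create(_["n_het"] = n_het, _["n_covered"] = bases_covered);
}
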