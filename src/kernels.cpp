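// Sequence kernels: k-mer counting, terminal-repeat scan, Hamming spacer scan,
// seed-and-extend read mapping, Markov sequence sampling, substitution errors.
// All randomness goes through R's RNG so set.seed() governs every kernel.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or anything else: breaks k-mer windows
  }
}

// Counts of all 4^k k-mers in lexicographic order (A<C<G<T), single strand,
// step-1 sliding window; windows containing a non-ACGT base are skipped.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(std::string seq, int k) {
  if (k < 1 || k > 10) stop("k must be between 1 and 10");
  const int n = (int) seq.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  IntegerVector counts((int)(1ULL << (2 * k)));
  uint64_t cur = 0;
  int run = 0;  // length of current valid-base run
  for (int i = 0; i < n; ++i) {
    int code = base_code(seq[i]);
    if (code < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) code) & mask;
    if (++run >= k) counts[(int) cur] += 1;
  }
  return counts;
}

// Largest L with 1 <= L <= n/2 such that prefix L == suffix L (exact chars),
// found via the Z-array in O(n); 0 when no such L exists.
// [[Rcpp::export]]
int cpp_detect_dtr(std::string s) {
  const int n = (int) s.size();
  if (n < 2) return 0;
  std::vector<int> z(n, 0);
  int l = 0, r = 0;
  for (int i = 1; i < n; ++i) {
    if (i < r) z[i] = std::min(r - i, z[i - l]);
    while (i + z[i] < n && s[z[i]] == s[i + z[i]]) ++z[i];
    if (i + z[i] > r) { l = i; r = i + z[i]; }
  }
  for (int L = n / 2; L >= 1; --L)
    if (z[n - L] >= L) return L;
  return 0;
}

// All windows of |pattern| in text with Hamming distance <= max_mm.
// Windows containing N (or any non-ACGT base) in the text are skipped.
// Returns 0-based positions.
// [[Rcpp::export]]
List cpp_hamming_scan(std::string text, std::string pattern, int max_mm) {
  const int n = (int) text.size(), m = (int) pattern.size();
  std::vector<int> pos, mm;
  if (m >= 1 && m <= n) {
    std::vector<int> ncum(n + 1, 0);
    for (int i = 0; i < n; ++i)
      ncum[i + 1] = ncum[i] + (base_code(text[i]) < 0 ? 1 : 0);
    for (int i = 0; i + m <= n; ++i) {
      if (ncum[i + m] - ncum[i] > 0) continue;
      int d = 0;
      for (int j = 0; j < m; ++j) {
        if (text[i + j] != pattern[j] && ++d > max_mm) break;
      }
      if (d <= max_mm) { pos.push_back(i); mm.push_back(d); }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["mm"] = wrap(mm));
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (char &c : out) c = comp_base(c);
  return out;
}

static inline uint64_t mix64(uint64_t x) {
  // splitmix64 finaliser
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Open-addressing seed index: kmer -> slice of a shared position array.
struct SeedIndex {
  int k;
  uint64_t tmask;                 // table size - 1 (power of two)
  std::vector<uint64_t> key;
  std::vector<int32_t> off;       // slot -> start offset into pos
  std::vector<int32_t> cnt;       // slot -> number of positions
  std::vector<int32_t> pos;       // concatenated positions, grouped by kmer
};

static void build_index(const std::string &ref, int k, SeedIndex &idx) {
  idx.k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int n = (int) ref.size();
  std::vector<std::pair<uint64_t, int32_t>> seeds;
  seeds.reserve(n > k ? (size_t)(n - k + 1) : 1);
  uint64_t cur = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int code = base_code(ref[i]);
    if (code < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) code) & mask;
    if (++run >= k) seeds.emplace_back(cur, (int32_t)(i - k + 1));
  }
  std::sort(seeds.begin(), seeds.end());
  size_t tsize = 16;
  while (tsize < 2 * seeds.size() + 2) tsize <<= 1;
  idx.tmask = tsize - 1;
  idx.key.assign(tsize, 0);
  idx.off.assign(tsize, -1);
  idx.cnt.assign(tsize, 0);
  idx.pos.resize(seeds.size());
  for (size_t i = 0; i < seeds.size();) {
    size_t j = i;
    while (j < seeds.size() && seeds[j].first == seeds[i].first) ++j;
    uint64_t slot = mix64(seeds[i].first) & idx.tmask;
    while (idx.off[slot] >= 0) slot = (slot + 1) & idx.tmask;
    idx.key[slot] = seeds[i].first;
    idx.off[slot] = (int32_t) i;
    idx.cnt[slot] = (int32_t)(j - i);
    for (size_t t = i; t < j; ++t) idx.pos[t] = seeds[t].second;
    i = j;
  }
}

static inline const int32_t *index_lookup(const SeedIndex &idx, uint64_t kmer,
                                          int32_t &count) {
  uint64_t slot = mix64(kmer) & idx.tmask;
  while (idx.off[slot] >= 0) {
    if (idx.key[slot] == kmer) {
      count = idx.cnt[slot];
      return idx.pos.data() + idx.off[slot];
    }
    slot = (slot + 1) & idx.tmask;
  }
  count = 0;
  return nullptr;
}

// Candidate placements (ref_start, 0-based) of `read` on the forward
// reference, as (position, seed-vote) pairs ordered by votes descending then
// position ascending. Seeds occurring more than MAX_SEED_OCC times in the
// reference are skipped (standard repetitive-seed limiting); if that leaves
// no candidate although shared seeds exist, the least-frequent shared seed's
// positions are used instead, so an error-free read always retains its true
// placement. At most MAX_CANDIDATES placements are returned.
#define MAX_SEED_OCC 16
#define MAX_CANDIDATES 128

static void seed_candidates(const std::string &read, const SeedIndex &idx,
                            std::vector<std::pair<int, int>> &out) {
  const int k = idx.k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t cur = 0;
  int run = 0;
  const int n = (int) read.size();
  std::vector<int> cands;
  int32_t best_occ = INT32_MAX;
  const int32_t *best_p = nullptr;
  int best_off = 0;
  for (int i = 0; i < n; ++i) {
    int code = base_code(read[i]);
    if (code < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) code) & mask;
    if (++run >= k) {
      int32_t cnt = 0;
      const int32_t *p = index_lookup(idx, cur, cnt);
      if (cnt == 0) continue;
      const int off = i - k + 1;
      if (cnt <= MAX_SEED_OCC) {
        for (int32_t t = 0; t < cnt; ++t) cands.push_back((int) p[t] - off);
      } else if (cnt < best_occ) {
        best_occ = cnt; best_p = p; best_off = off;
      }
    }
  }
  if (cands.empty() && best_p != nullptr) {
    for (int32_t t = 0; t < best_occ; ++t)
      cands.push_back((int) best_p[t] - best_off);
  }
  std::sort(cands.begin(), cands.end());
  out.clear();
  for (size_t i = 0; i < cands.size();) {
    size_t j = i;
    while (j < cands.size() && cands[j] == cands[i]) ++j;
    out.emplace_back(cands[i], (int)(j - i));
    i = j;
  }
  std::sort(out.begin(), out.end(), [](const std::pair<int, int> &a,
                                       const std::pair<int, int> &b) {
    if (a.second != b.second) return a.second > b.second;
    return a.first < b.first;
  });
  if (out.size() > MAX_CANDIDATES) out.resize(MAX_CANDIDATES);
}

// Hamming distance of read placed end-to-end at ref[start .. start+len);
// N never matches anything.
static int placement_mismatches(const std::string &ref, const std::string &read,
                                int start, int best_so_far) {
  int d = 0;
  const int m = (int) read.size();
  for (int j = 0; j < m; ++j) {
    char a = ref[start + j], b = read[j];
    if (a != b || base_code(a) < 0) {
      if (++d > best_so_far) return d;  // early abort: can't beat current best
    }
  }
  return d;
}

// Best ungapped end-to-end placement per read on one reference.
// A read maps when it shares >= 1 exact seed of length seed_len with the
// reference (either orientation) and its best seed-anchored placement has
// identity >= min_identity. Ties: highest identity, then leftmost ref_start,
// then '+' strand. Returns one row per mapped read:
//   read (1-based input index), start (0-based), strand, mismatches, identity.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string ref,
                        int seed_len, double min_identity) {
  const int rn = (int) ref.size();
  if (seed_len < 1 || seed_len > 31) stop("seed_len must be between 1 and 31");
  if (rn < seed_len) stop("reference shorter than seed_len");
  SeedIndex idx;
  build_index(ref, seed_len, idx);

  std::vector<int> out_read, out_start, out_mm, out_len;
  std::vector<std::string> out_strand;
  std::vector<double> out_ident;
  std::vector<std::pair<int, int>> cands;

  for (int i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int m = (int) fwd.size();
    if (m < seed_len || m > rn) continue;
    std::string rev = revcomp(fwd);

    int best_mm = m + 1, best_start = -1;
    char best_strand = '+';
    for (int s = 0; s < 2; ++s) {
      const std::string &q = (s == 0) ? fwd : rev;
      seed_candidates(q, idx, cands);
      for (const auto &cand : cands) {
        const int start = cand.first;
        if (start < 0 || start + m > rn) continue;
        int d = placement_mismatches(ref, q, start, best_mm);
        bool better = d < best_mm ||
          (d == best_mm && best_start >= 0 &&
           (start < best_start ||
            (start == best_start && s == 0 && best_strand == '-')));
        if (better) { best_mm = d; best_start = start; best_strand = (s == 0) ? '+' : '-'; }
      }
    }
    if (best_start < 0) continue;
    double ident = 1.0 - (double) best_mm / (double) m;
    if (ident + 1e-12 < min_identity) continue;
    out_read.push_back(i + 1);
    out_start.push_back(best_start);
    out_strand.push_back(std::string(1, best_strand));
    out_mm.push_back(best_mm);
    out_ident.push_back(ident);
    out_len.push_back(m);
  }
  return DataFrame::create(_["read"] = wrap(out_read),
                           _["start"] = wrap(out_start),
                           _["strand"] = wrap(out_strand),
                           _["mismatches"] = wrap(out_mm),
                           _["identity"] = wrap(out_ident),
                           _["aligned_length"] = wrap(out_len),
                           _["stringsAsFactors"] = false);
}

// Sample a sequence of length n from an order-`order` Markov model.
// probs: (4^order) x 4 row-stochastic matrix, rows indexed by the 2-bit code
// of the previous `order` bases (first base most significant). The first
// `order` bases are drawn uniformly. Uses R's RNG.
// [[Rcpp::export]]
std::string cpp_sample_markov(int n, int order, NumericMatrix probs) {
  if (n < 1) stop("length must be >= 1");
  if (order < 0 || order > 8) stop("order must be between 0 and 8");
  const int nrow = 1 << (2 * order);
  if (probs.nrow() != nrow || probs.ncol() != 4)
    stop("probs must be a 4^order x 4 matrix");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const uint64_t mask = order > 0 ? ((1ULL << (2 * order)) - 1) : 0;
  std::string out;
  out.reserve(n);
  uint64_t ctx = 0;
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    int code;
    if (i < order) {
      code = (int) (unif_rand() * 4.0);
      if (code > 3) code = 3;
    } else {
      const double u = unif_rand();
      double acc = 0.0;
      code = 3;
      const int row = (int) ctx;
      for (int b = 0; b < 4; ++b) {
        acc += probs(row, b);
        if (u < acc) { code = b; break; }
      }
    }
    out.push_back(bases[code]);
    if (order > 0) ctx = ((ctx << 2) | (uint64_t) code) & mask;
  }
  PutRNGstate();
  return out;
}

// Independent per-base substitution errors at `rate`; the substituted base is
// always different from the original. Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(reads.size());
  GetRNGstate();
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    if (rate > 0) {
      const int m = (int) r.size();
      int nerr = (int) R::rbinom((double) m, rate);
      for (int e = 0; e < nerr; ++e) {
        int p = (int) (unif_rand() * m);
        if (p >= m) p = m - 1;
        int code = base_code(r[p]);
        int shift = 1 + (int) (unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        if (code < 0) code = (int) (unif_rand() * 4.0) % 4;
        r[p] = bases[(code + shift) % 4];
      }
    }
    out[i] = r;
  }
  PutRNGstate();
  return out;
}
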