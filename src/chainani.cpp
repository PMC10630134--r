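#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <cmath>
#include <string>

using namespace Rcpp;

// Invertible 64-bit mixer (splitmix64 finalizer). Any fixed invertible mixer
// is acceptable here; invertibility guarantees distinct k-mers get distinct
// hashes, so hash equality == canonical k-mer equality.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string hash_hex(uint64_t h) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long) h);
  return std::string(buf);
}

static uint64_t parse_hex(const std::string& s) {
  // hand-rolled to avoid strtoull (maps to a glibc-2.38-only alias under
  // newer toolchains)
  uint64_t v = 0;
  for (char c : s) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else break;
    v = (v << 4) | (uint64_t) d;
  }
  return v;
}

// floor(2^64 / rate) as the FracMinHash selection threshold; select iff
// h < threshold. rate <= 1 selects everything (threshold is the full range).
struct FmhThreshold {
  uint64_t thr;
  bool all;
};

static FmhThreshold fmh_threshold(double rate) {
  FmhThreshold t;
  if (rate <= 1.0) { t.thr = UINT64_MAX; t.all = true; return t; }
  t.all = false;
  if (rate == std::floor(rate) && rate < 9.0e18) {
    uint64_t g = (uint64_t) rate;
    uint64_t q = UINT64_MAX / g;
    uint64_t r = UINT64_MAX % g;
    if (r + 1ULL == g) q += 1ULL;  // exact floor(2^64/g)
    t.thr = q;
  } else {
    t.thr = (uint64_t) std::ldexp(1.0 / rate, 64);
  }
  return t;
}

// [[Rcpp::export(name = ".fmh_select_cpp")]]
LogicalVector fmh_select_cpp(CharacterVector hash, double rate) {
  FmhThreshold t = fmh_threshold(rate);
  R_xlen_t n = hash.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(hash[i])) { out[i] = NA_LOGICAL; continue; }
    uint64_t h = parse_hex(as<std::string>(hash[i]));
    out[i] = t.all || (h < t.thr);
  }
  return out;
}

// Canonical hash of each k-mer string: hash the numerically smaller of the
// 2-bit encodings of the k-mer and its reverse complement (A<C<G<T).
// strand = 0 if the forward encoding won (ties included), 1 otherwise.
// Ambiguous (non-ACGT) k-mers yield NA.
// [[Rcpp::export(name = ".kmer_hash_cpp")]]
List kmer_hash_cpp(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector hash(n);
  IntegerVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    size_t k = s.size();
    if (k == 0 || k > 31) stop("k-mer length must be in 1..31");
    uint64_t fwd = 0, rc = 0;
    bool ok = true;
    for (size_t j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t) c;
      rc |= ((uint64_t) (3 - c)) << (2 * j);
    }
    if (!ok) { hash[i] = NA_STRING; strand[i] = NA_INTEGER; continue; }
    uint64_t canon = (fwd <= rc) ? fwd : rc;
    hash[i] = hash_hex(mix64(canon));
    strand[i] = (fwd <= rc) ? 0 : 1;
  }
  return List::create(_["hash"] = hash, _["strand"] = strand);
}

// One pass over a contig: rolling 2-bit encoding of every k-length window,
// canonical hashing, FracMinHash selection at `rate`. Windows containing any
// non-ACGT base are skipped. Positions are 0-based window starts.
// [[Rcpp::export(name = ".fmh_seeds_cpp")]]
List fmh_seeds_cpp(std::string seq, int k, double rate) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  FmhThreshold t = fmh_threshold(rate);
  size_t n = seq.size();
  std::vector<std::string> hash;
  std::vector<int> pos;
  std::vector<int> strand;
  if ((int) n < k) {
    return List::create(_["hash"] = wrap(hash), _["pos"] = wrap(pos),
                        _["strand"] = wrap(strand));
  }
  uint64_t mask = (k == 32) ? UINT64_MAX : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // number of consecutive valid bases ending at i
  int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rc = (rc >> 2) | (((uint64_t) (3 - c)) << shift);
    if (++valid >= k) {
      uint64_t canon = (fwd <= rc) ? fwd : rc;
      uint64_t h = mix64(canon);
      if (t.all || h < t.thr) {
        hash.push_back(hash_hex(h));
        pos.push_back((int) (i + 1 - k));
        strand.push_back((fwd <= rc) ? 0 : 1);
      }
    }
  }
  return List::create(_["hash"] = wrap(hash), _["pos"] = wrap(pos),
                      _["strand"] = wrap(strand));
}

// Banded chaining DP over anchors sorted lexicographically by (x, y).
// f(i) = max(max_j f(j) + 20 - |(y_i-y_j) - (x_i-x_j)|, 0) over strict
// predecessors (x_j < x_i, y_j < y_i); at most `a_band` predecessors are
// scanned and the scan stops once x_i - x_j > b_band. pred is 1-based, 0 when
// f(i) = 0. Ties in the argmax go to the smallest j.
// [[Rcpp::export(name = ".chain_dp_cpp")]]
List chain_dp_cpp(IntegerVector x, IntegerVector y, int a_band, double b_band) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  NumericVector f(n);
  IntegerVector pred(n);
  if (a_band < 1) a_band = 1;
  for (int i = 0; i < n; ++i) {
    double best = R_NegInf;
    int bestj = 0;
    int lo = i - a_band;
    if (lo < 0) lo = 0;
    for (int j = i - 1; j >= lo; --j) {
      if ((double) (x[i] - x[j]) > b_band) break;
      if (x[j] < x[i] && y[j] < y[i]) {
        double gap = std::fabs((double) (y[i] - y[j]) - (double) (x[i] - x[j]));
        double s = f[j] + 20.0 - gap;
        if (s >= best) { best = s; bestj = j + 1; }  // descending j: >= keeps smallest j
      }
    }
    if (best > 0.0) { f[i] = best; pred[i] = bestj; }
    else            { f[i] = 0.0;  pred[i] = 0; }
  }
  return List::create(_["f"] = f, _["pred"] = pred);
}
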