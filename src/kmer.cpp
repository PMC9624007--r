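#include <Rcpp.h>
#include <cstdint>
#include <queue>
#include <deque>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Hashes live in the low 53 bits so every value is exactly representable in
// an R double. Identity mode exposes the canonical 2-bit encoding directly
// (A=0, C=1, G=2, T=3, big-endian), so it is injective for k <= 26.
static const uint64_t MASK53 = ((uint64_t)1 << 53) - 1;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Rolling scan over one sequence: canonical k-mer code at every ACGT-only
// window, hashed with the seeded finalizer (or returned raw in identity
// mode). Returns 0-based start positions and hash values as doubles.
// [[Rcpp::export]]
List kmer_scan_cpp(std::string seq, int k, double seed, bool identity) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (identity && k > 26)
    stop("identity hashing is exact only for k <= 26");
  size_t n = seq.size();
  std::vector<int> pos;
  std::vector<double> hash;
  if (n < (size_t)k) return List::create(_["pos"] = IntegerVector(0),
                                         _["hash"] = NumericVector(0));
  uint64_t smix = splitmix64((uint64_t)(int64_t)seed);
  uint64_t fmask = (k == 32) ? ~(uint64_t)0 : (((uint64_t)1 << (2 * k)) - 1);
  int rshift = 2 * (k - 1);
  uint64_t f = 0, r = 0;
  int run = 0;  // length of current ACGT run ending at i
  pos.reserve(n - k + 1);
  hash.reserve(n - k + 1);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t)c) & fmask;
    r = (r >> 2) | ((uint64_t)(3 - c) << rshift);
    if (++run >= k) {
      uint64_t canon = f < r ? f : r;
      uint64_t h = identity ? canon : (splitmix64(canon ^ smix) & MASK53);
      pos.push_back((int)(i - k + 1));
      hash.push_back((double)h);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["hash"] = wrap(hash));
}

// Bottom-s distinct hashes in one pass: bounded max-heap plus a membership
// set, memory proportional to s. Returns the s smallest distinct values,
// sorted ascending.
// [[Rcpp::export]]
NumericVector bottom_s_cpp(NumericVector hashes, int s) {
  if (s < 1) stop("s must be >= 1");
  std::priority_queue<uint64_t> heap;  // max-heap
  std::unordered_set<uint64_t> in_heap;
  for (R_xlen_t i = 0; i < hashes.size(); ++i) {
    uint64_t h = (uint64_t)hashes[i];
    if (in_heap.count(h)) continue;
    if ((int)heap.size() < s) {
      heap.push(h); in_heap.insert(h);
    } else if (h < heap.top()) {
      in_heap.erase(heap.top()); heap.pop();
      heap.push(h); in_heap.insert(h);
    }
  }
  int m = (int)heap.size();
  NumericVector out(m);
  for (int i = m - 1; i >= 0; --i) { out[i] = (double)heap.top(); heap.pop(); }
  return out;
}

// Windowed minimizers over an array of consecutive k-mer hashes: every
// window of w entries contributes its minimum, leftmost on ties. Returns
// 0-based indices into the input array, distinct and ascending. If the
// array is shorter than w a single window covers it.
// [[Rcpp::export]]
IntegerVector minimizer_indices_cpp(NumericVector hashes, int w) {
  int m = (int)hashes.size();
  if (m == 0) return IntegerVector(0);
  if (w < 1) stop("window must be >= 1");
  if (w > m) w = m;
  std::deque<int> dq;  // indices, hashes increasing; front = window minimum
  std::vector<int> sel;
  for (int i = 0; i < m; ++i) {
    // strict comparison keeps the earlier of equal hashes at the front
    while (!dq.empty() && hashes[dq.back()] > hashes[i]) dq.pop_back();
    dq.push_back(i);
    if (dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1) {
      int j = dq.front();
      if (sel.empty() || sel.back() != j) sel.push_back(j);
    }
  }
  return wrap(sel);
}
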