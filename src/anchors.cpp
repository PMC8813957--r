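#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base code; -1 for anything that is not A/C/G/T
static inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Maximal exact matches between ref and qry, seeded by k-mers that occur
// exactly once in ref. Exact 2-bit encoding (no hash collisions), k <= 31.
// Per-diagonal sweep guarantees each maximal match is reported once.
// Coordinates are 0-based; strand handling is the caller's job.
// [[Rcpp::export(name = ".anchors_cpp")]]
DataFrame anchors_cpp(std::string ref, std::string qry, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  const int64_t nr = (int64_t)ref.size(), nq = (int64_t)qry.size();
  std::vector<int64_t> ref_start, qry_start, alen;
  if (nr < k || nq < k) {
    return DataFrame::create(_["ref_start"] = NumericVector(0),
                             _["qry_start"] = NumericVector(0),
                             _["length"]    = NumericVector(0));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index: kmer -> position if unique in ref, -2 if repeated
  std::unordered_map<uint64_t, int64_t> idx;
  idx.reserve((size_t)nr * 2);
  {
    uint64_t h = 0; int valid = 0;
    for (int64_t i = 0; i < nr; ++i) {
      int b = base2(ref[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int64_t pos = i - k + 1;
        auto it = idx.find(h);
        if (it == idx.end()) idx.emplace(h, pos);
        else it->second = -2;
      }
    }
  }

  // per-diagonal high-water mark: qry position up to which the diagonal is
  // already covered by a reported match (diag = ref_pos - qry_pos)
  std::unordered_map<int64_t, int64_t> diag_done;

  uint64_t h = 0; int valid = 0;
  for (int64_t j = 0; j < nq; ++j) {
    int b = base2(qry[j]);
    if (b < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int64_t q = j - k + 1;
    auto it = idx.find(h);
    if (it == idx.end() || it->second < 0) continue;
    int64_t r = it->second;
    int64_t diag = r - q;
    auto dd = diag_done.find(diag);
    if (dd != diag_done.end() && q < dd->second) continue;
    // extend left
    int64_t rl = r, ql = q;
    while (rl > 0 && ql > 0) {
      int a1 = base2(ref[rl - 1]), a2 = base2(qry[ql - 1]);
      if (a1 < 0 || a1 != a2) break;
      --rl; --ql;
    }
    // extend right
    int64_t re = r + k, qe = q + k;
    while (re < nr && qe < nq) {
      int a1 = base2(ref[re]), a2 = base2(qry[qe]);
      if (a1 < 0 || a1 != a2) break;
      ++re; ++qe;
    }
    ref_start.push_back(rl);
    qry_start.push_back(ql);
    alen.push_back(re - rl);
    diag_done[diag] = qe;
  }

  return DataFrame::create(
    _["ref_start"] = NumericVector(ref_start.begin(), ref_start.end()),
    _["qry_start"] = NumericVector(qry_start.begin(), qry_start.end()),
    _["length"]    = NumericVector(alen.begin(), alen.end()));
}

// Per-position read depth from interval placements (0-based half-open).
// [[Rcpp::export(name = ".interval_depth_cpp")]]
IntegerVector interval_depth_cpp(NumericVector starts, NumericVector ends, int chrom_len) {
  IntegerVector depth(chrom_len);
  std::vector<int> diff(chrom_len + 1, 0);
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    int64_t s = (int64_t)starts[i], e = (int64_t)ends[i];
    if (s < 0) s = 0;
    if (e > chrom_len) e = chrom_len;
    if (s >= e) continue;
    diff[s] += 1; diff[e] -= 1;
  }
  int cum = 0;
  for (int i = 0; i < chrom_len; ++i) { cum += diff[i]; depth[i] = cum; }
  return depth;
}
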