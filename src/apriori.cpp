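#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_set>
using namespace Rcpp;

// Carrier sets are kept as packed 64-bit bitsets over patient indices so that
// itemset counting is a block-wise AND + popcount. Candidate generation is the
// classic F(k-1) x F(k-1) prefix join with full subset pruning.

typedef std::vector<uint64_t> bitvec;

static inline int popcnt(const bitvec& v) {
  long long s = 0;
  for (size_t i = 0; i < v.size(); ++i) s += __builtin_popcountll(v[i]);
  return (int)s;
}

static inline void and_into(const bitvec& a, const bitvec& b, bitvec& out) {
  for (size_t i = 0; i < a.size(); ++i) out[i] = a[i] & b[i];
}

static inline int popcnt_and(const bitvec& a, const bitvec& b) {
  long long s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += __builtin_popcountll(a[i] & b[i]);
  return (int)s;
}

static std::string set_key(const std::vector<int>& items) {
  std::string k;
  k.reserve(items.size() * sizeof(int));
  for (size_t i = 0; i < items.size(); ++i)
    k.append(reinterpret_cast<const char*>(&items[i]), sizeof(int));
  return k;
}

// Frequent antecedent search with a fixed 0/1 consequent counted alongside.
// x: patients x items 0/1 matrix; died: 0/1 vector of length nrow(x).
// Returns, per order k = 1..max_order, a matrix of 1-based item indices
// (rows = itemsets, sorted ascending within a row), the carrier count and
// the carriers-who-died count.
// [[Rcpp::export(name = ".apriori_mine")]]
List apriori_mine(IntegerMatrix x, IntegerVector died,
                  int min_count, int max_order) {
  const int n = x.nrow(), m = x.ncol();
  if (min_count < 1) stop("min_count must be >= 1");
  if (max_order < 1) stop("max_order must be >= 1");
  const int nb = (n + 63) / 64;

  bitvec dead(nb, 0);
  for (int i = 0; i < n; ++i)
    if (died[i] == 1) dead[i >> 6] |= (uint64_t)1 << (i & 63);

  // Level 1
  std::vector<std::vector<int> > sets;       // current level itemsets
  std::vector<bitvec> carr;                  // their carrier bitsets
  std::vector<int> cnt, cntd;
  for (int j = 0; j < m; ++j) {
    bitvec v(nb, 0);
    int c = 0;
    for (int i = 0; i < n; ++i) {
      if (x(i, j) == 1) { v[i >> 6] |= (uint64_t)1 << (i & 63); ++c; }
    }
    if (c >= min_count) {
      sets.push_back(std::vector<int>(1, j));
      cnt.push_back(c);
      cntd.push_back(popcnt_and(v, dead));
      carr.push_back(v);
    }
  }

  List out;
  {
    IntegerMatrix im(sets.size(), 1);
    IntegerVector cv(sets.size()), dv(sets.size());
    for (size_t r = 0; r < sets.size(); ++r) {
      im(r, 0) = sets[r][0] + 1; cv[r] = cnt[r]; dv[r] = cntd[r];
    }
    out.push_back(List::create(_["items"] = im, _["count"] = cv,
                               _["count_died"] = dv));
  }

  for (int k = 2; k <= max_order && sets.size() >= 2; ++k) {
    std::unordered_set<std::string> prev_keys;
    prev_keys.reserve(sets.size() * 2);
    for (size_t r = 0; r < sets.size(); ++r) prev_keys.insert(set_key(sets[r]));

    std::vector<std::vector<int> > nsets;
    std::vector<bitvec> ncarr;
    std::vector<int> ncnt, ncntd;
    const bool keep_bits = (k < max_order);
    bitvec tmp(nb);

    // itemsets at the previous level are generated in lexicographic index
    // order, so the prefix-join scan over [i, j) ranges is valid
    size_t i = 0;
    while (i < sets.size()) {
      size_t j = i + 1;
      while (j < sets.size() &&
             std::equal(sets[i].begin(), sets[i].end() - 1, sets[j].begin()))
        ++j;
      for (size_t a = i; a < j; ++a) {
        for (size_t b = a + 1; b < j; ++b) {
          std::vector<int> cand(sets[a]);
          cand.push_back(sets[b].back());
          // subset pruning: every (k-1)-subset must be frequent
          bool ok = true;
          if (k > 2) {
            std::vector<int> sub(cand.size() - 1);
            for (size_t drop = 0; ok && drop + 2 < cand.size(); ++drop) {
              size_t p = 0;
              for (size_t q = 0; q < cand.size(); ++q)
                if (q != drop) sub[p++] = cand[q];
              if (!prev_keys.count(set_key(sub))) ok = false;
            }
          }
          if (!ok) continue;
          and_into(carr[a], carr[b], tmp);
          int c = popcnt(tmp);
          if (c < min_count) continue;
          nsets.push_back(cand);
          ncnt.push_back(c);
          ncntd.push_back(popcnt_and(tmp, dead));
          if (keep_bits) ncarr.push_back(tmp);
        }
      }
      i = j;
    }

    IntegerMatrix im(nsets.size(), k);
    IntegerVector cv(nsets.size()), dv(nsets.size());
    for (size_t r = 0; r < nsets.size(); ++r) {
      for (int q = 0; q < k; ++q) im(r, q) = nsets[r][q] + 1;
      cv[r] = ncnt[r]; dv[r] = ncntd[r];
    }
    out.push_back(List::create(_["items"] = im, _["count"] = cv,
                               _["count_died"] = dv));

    sets.swap(nsets);
    carr.swap(ncarr);
    cnt.swap(ncnt);
    cntd.swap(ncntd);
    if (!keep_bits) break;
  }
  return out;
}

// FNV-1a 64-bit hash of a raw vector, as a hex string (used for config
// provenance stamps).
// [[Rcpp::export(name = ".fnv1a64")]]
std::string fnv1a64(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
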