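// Compact rank store for genome-scale guide-cluster extraction.
//
// The full co-expression rank matrix of an n-gene compendium is n x n; at
// array-genome scale (n ~ 30k) a native integer matrix plus its transient
// copies does not fit in a workstation's memory. Ranks are bounded by
// n - 1 < 2^16, so they are held here as a single uint16 buffer (column g =
// gene g's ranking of every other gene, 0 at the diagonal), filled block by
// block from correlation slabs computed in R, and consumed by a tiled
// top-k pass that never materializes the HRR matrix.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint16_t> RankStore;

// [[Rcpp::export]]
SEXP rank_store_create(int n) {
  if (n < 2 || n > 65535)
    stop("rank store supports 2..65535 genes");
  XPtr<RankStore> p(new RankStore((size_t)n * (size_t)n, 0), true);
  p.attr("n") = n;
  return p;
}

// corr_block: b x n slab, row r = correlations of gene cols[r] against all
// genes. idr: 1-based lexicographic rank of each gene id (tie-break).
// [[Rcpp::export]]
void rank_store_fill(SEXP ptr, NumericMatrix corr_block, IntegerVector cols,
                     IntegerVector idr) {
  XPtr<RankStore> p(ptr);
  const int n = as<int>(p.attr("n"));
  if (corr_block.ncol() != n || idr.size() != n)
    stop("slab dimensions do not match the store");
  const int b = corr_block.nrow();
  if (cols.size() != b) stop("cols must index the slab rows");
  struct Key { double v; int32_t idr; int32_t j; };
  std::vector<Key> keys(n);
  for (int r = 0; r < b; ++r) {
    const int self = cols[r] - 1;
    if (self < 0 || self >= n) stop("column index out of range");
    for (int j = 0; j < n; ++j)
      keys[j] = Key{corr_block(r, j), idr[j], j};
    keys[self].v = -1e308;  // self sorts last, never ranked
    std::sort(keys.begin(), keys.end(), [](const Key& a, const Key& c) {
      if (a.v != c.v) return a.v > c.v;   // rank 1 = highest r
      return a.idr < c.idr;               // ties: ascending identifier
    });
    uint16_t* col = p->data() + (size_t)self * (size_t)n;
    for (int j = 0; j < n; ++j) col[keys[j].j] = (uint16_t)(j + 1);
    col[self] = 0;
  }
}

// full rank matrix back (testing / moderate n)
// [[Rcpp::export]]
IntegerMatrix rank_store_dense(SEXP ptr) {
  XPtr<RankStore> p(ptr);
  const int n = as<int>(p.attr("n"));
  IntegerMatrix out(n, n);
  for (int g = 0; g < n; ++g) {
    const uint16_t* col = p->data() + (size_t)g * (size_t)n;
    for (int j = 0; j < n; ++j) out(j, g) = col[j];
  }
  return out;
}

// Top-k co-expressed partners per guide by HRR = max(rank(g,j), rank(j,g)),
// ties by ascending HRR, then the guide's own rank of the candidate, then
// identifier. Returns 1-based member indices and their HRR values (k x n).
// [[Rcpp::export]]
List rank_store_topk(SEXP ptr, int k, IntegerVector idr, int tile = 256) {
  XPtr<RankStore> p(ptr);
  const int n = as<int>(p.attr("n"));
  if (idr.size() != n) stop("idr length mismatch");
  const int kk = std::min(k, n - 1);
  IntegerMatrix members(kk, n), hrr(kk, n);
  std::vector<uint16_t> rowbuf((size_t)tile * (size_t)n);
  // packed selection key: (hrr, guide's own rank, identifier rank), all
  // <= 2^16, compared as a single integer; idr is a permutation, so the
  // low 16 bits identify the candidate via the inverse permutation
  std::vector<uint64_t> key(n);
  std::vector<int> inv_idr(n + 1);
  for (int j = 0; j < n; ++j) inv_idr[idr[j]] = j + 1;
  for (int t0 = 0; t0 < n; t0 += tile) {
    const int tb = std::min(tile, n - t0);
    // gather rows t0..t0+tb-1 of the rank matrix (rank(j, g) entries)
    for (int j = 0; j < n; ++j) {
      const uint16_t* col = p->data() + (size_t)j * (size_t)n;
      for (int t = 0; t < tb; ++t)
        rowbuf[(size_t)t * n + j] = col[t0 + t];
    }
    for (int t = 0; t < tb; ++t) {
      const int g = t0 + t;
      const uint16_t* colg = p->data() + (size_t)g * (size_t)n;
      const uint16_t* rowg = rowbuf.data() + (size_t)t * n;
      for (int j = 0; j < n; ++j) {
        const uint64_t h = colg[j] > rowg[j] ? colg[j] : rowg[j];
        key[j] = (h << 32) | ((uint64_t)colg[j] << 16) | (uint64_t)idr[j];
      }
      key[g] = (uint64_t)n << 32;  // exceeds any attainable HRR (n - 1)
      std::nth_element(key.begin(), key.begin() + kk, key.end());
      std::sort(key.begin(), key.begin() + kk);
      for (int j = 0; j < kk; ++j) {
        members(j, g) = inv_idr[(int)(key[j] & 0xffff)];
        hrr(j, g) = (int)(key[j] >> 32);
      }
    }
  }
  return List::create(_["members"] = members, _["hrr"] = hrr);
}
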