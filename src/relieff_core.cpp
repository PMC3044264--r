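#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Genotype matrices are passed SNP-major (N SNPs x M samples) so that one
// sample is one contiguous column of the column-major storage.

// [[Rcpp::export(name = ".hamming_dist_cpp")]]
IntegerMatrix hamming_dist_cpp(const IntegerMatrix& gt) {
  const int n = gt.nrow(), m = gt.ncol();
  IntegerMatrix d(m, m);
  const int* g = INTEGER(gt);
  // byte-packed copy: the kernel is memory-bound
  std::vector<unsigned char> p((size_t)n * m);
  for (R_xlen_t q = 0; q < (R_xlen_t)n * m; ++q)
    p[q] = (unsigned char)g[q];
  for (int a = 0; a < m; ++a) {
    const unsigned char* ga = p.data() + (size_t)a * n;
    for (int b = a + 1; b < m; ++b) {
      const unsigned char* gb = p.data() + (size_t)b * n;
      int acc = 0;
      for (int j = 0; j < n; ++j) acc += (ga[j] != gb[j]);
      d(a, b) = acc;
      d(b, a) = acc;
    }
  }
  return d;
}

// Select, for one target, the K nearest same-class ("hit") and K nearest
// other-class ("miss") samples by (distance, current position) order --
// the "first-K" rule that reproduces the sample-order dependence of the
// classic implementation.  A side is flagged tied when more than K
// candidates lie at or within the distance of its K-th neighbour.
struct NeighborPick {
  std::vector<int> hits, misses;
  bool tie_hit, tie_miss;
};

static NeighborPick pick_neighbors(const int* drow, const IntegerVector& labels,
                                   int target, int K) {
  const int m = labels.size();
  std::vector<std::pair<int,int> > same, other; // (distance, index)
  same.reserve(m); other.reserve(m);
  for (int b = 0; b < m; ++b) {
    if (b == target) continue;
    if (labels[b] == labels[target]) same.push_back(std::make_pair(drow[b], b));
    else other.push_back(std::make_pair(drow[b], b));
  }
  NeighborPick out;
  out.tie_hit = out.tie_miss = false;
  if ((int)same.size() < K || (int)other.size() < K) {
    stop("class too small for K nearest neighbours");
  }
  std::partial_sort(same.begin(), same.begin() + K, same.end());
  std::partial_sort(other.begin(), other.begin() + K, other.end());
  out.hits.resize(K); out.misses.resize(K);
  for (int k = 0; k < K; ++k) { out.hits[k] = same[k].second; out.misses[k] = other[k].second; }
  int dk = same[K - 1].first;
  int cnt = 0;
  for (size_t q = 0; q < same.size(); ++q) if (same[q].first <= dk) ++cnt;
  out.tie_hit = cnt > K;
  dk = other[K - 1].first;
  cnt = 0;
  for (size_t q = 0; q < other.size(); ++q) if (other[q].first <= dk) ++cnt;
  out.tie_miss = cnt > K;
  return out;
}

// ReliefF weight accumulation with exact integer numerators: the returned
// weight is num/(Mt*K) where num is an integer, so permuting a tie-free
// dataset reproduces bit-identical weights.
// targets: 0-based indices of the samples to evaluate, in evaluation order.
// [[Rcpp::export(name = ".relieff_core_cpp")]]
List relieff_core_cpp(const IntegerMatrix& gt, const IntegerMatrix& dist,
                      const IntegerVector& labels, int K,
                      const IntegerVector& targets) {
  const int n = gt.nrow(), m = gt.ncol();
  const int mt = targets.size();
  std::vector<long long> num(n, 0);
  LogicalVector tie_hit(m, false), tie_miss(m, false);
  const int* g = INTEGER(gt);
  const int* d = INTEGER(dist);
  for (int t = 0; t < mt; ++t) {
    const int i = targets[t];
    NeighborPick nb = pick_neighbors(d + (R_xlen_t)i * m, labels, i, K);
    tie_hit[i] = nb.tie_hit;
    tie_miss[i] = nb.tie_miss;
    const int* gi = g + (R_xlen_t)i * n;
    for (int k = 0; k < K; ++k) {
      const int* gh = g + (R_xlen_t)nb.hits[k] * n;
      const int* gm = g + (R_xlen_t)nb.misses[k] * n;
      for (int j = 0; j < n; ++j)
        num[j] += (gi[j] != gm[j]) - (gi[j] != gh[j]);
    }
  }
  NumericVector w(n);
  const double denom = (double)mt * (double)K;
  for (int j = 0; j < n; ++j) w[j] = num[j] / denom;
  return List::create(_["weights"] = w,
                      _["tie_hit"] = tie_hit,
                      _["tie_miss"] = tie_miss);
}

// Count the (target, side, iteration) neighbour ties along a full TuRF
// path: R ReliefF passes with removal of floor(N/R) lowest-weighted SNPs
// after each of the first R-1 passes (weight ties removed highest-index
// first). Mirrors turf_ranking exactly but only counts ties; used by the
// tie-removal subset search where it is evaluated many thousands of times.
// Also reports, per sample, how many tie events it participates in (as the
// target or as one of the equidistant boundary candidates), which lets the
// subset search direct its moves at the samples actually causing ties.
// [[Rcpp::export(name = ".turf_tie_count_cpp")]]
List turf_tie_count_cpp(const IntegerMatrix& gt, const IntegerVector& labels,
                        int K, int R) {
  const int n = gt.nrow(), m = gt.ncol();
  const int* g = INTEGER(gt);
  std::vector<int> dist((size_t)m * m, 0);
  std::vector<bool> alive(n, true);
  for (int a = 0; a < m; ++a) {
    const int* ga = g + (R_xlen_t)a * n;
    for (int b = a + 1; b < m; ++b) {
      const int* gb = g + (R_xlen_t)b * n;
      int acc = 0;
      for (int j = 0; j < n; ++j) acc += (ga[j] != gb[j]);
      dist[a * m + b] = acc;
      dist[b * m + a] = acc;
    }
  }
  const int n_remove = n / R;
  int ties = 0;
  IntegerVector part(m);
  std::vector<long long> num(n);
  std::vector<int> drow(m);
  // credit the target and every boundary-equidistant candidate of a tied side
  auto credit = [&](int i, bool same_side) {
    int cnt = 0, dk = -1;
    std::vector<std::pair<int,int> > cand;
    for (int b = 0; b < m; ++b) {
      if (b == i) continue;
      if ((labels[b] == labels[i]) == same_side)
        cand.push_back(std::make_pair(drow[b], b));
    }
    std::sort(cand.begin(), cand.end());
    dk = cand[K - 1].first;
    ++part[i];
    for (size_t q = 0; q < cand.size(); ++q)
      if (cand[q].first == dk) { ++part[cand[q].second]; ++cnt; }
    (void)cnt;
  };
  std::vector<int> alive_idx(n);
  for (int j = 0; j < n; ++j) alive_idx[j] = j;
  for (int iter = 1; iter <= R; ++iter) {
    const int na = (int)alive_idx.size();
    std::fill(num.begin(), num.begin() + na, 0LL);
    for (int i = 0; i < m; ++i) {
      for (int b = 0; b < m; ++b) drow[b] = dist[(size_t)i * m + b];
      NeighborPick nb = pick_neighbors(drow.data(), labels, i, K);
      if (nb.tie_hit) { ++ties; credit(i, true); }
      if (nb.tie_miss) { ++ties; credit(i, false); }
      const int* gi = g + (R_xlen_t)i * n;
      for (int k = 0; k < K; ++k) {
        const int* gh = g + (R_xlen_t)nb.hits[k] * n;
        const int* gm = g + (R_xlen_t)nb.misses[k] * n;
        for (int q = 0; q < na; ++q) {
          const int j = alive_idx[q];
          num[q] += (gi[j] != gm[j]) - (gi[j] != gh[j]);
        }
      }
    }
    if (iter == R) break;
    // remove the n_remove lowest-weighted alive SNPs (ties: higher index)
    std::vector<std::pair<long long, int> > key;
    key.reserve(na);
    for (int q = 0; q < na; ++q)
      key.push_back(std::make_pair(num[q], -alive_idx[q]));
    std::sort(key.begin(), key.end());
    for (int q = 0; q < n_remove && q < (int)key.size(); ++q) {
      const int j = -key[q].second;
      alive[j] = false;
      // subtract this SNP's contribution from all pairwise distances
      for (int a = 0; a < m; ++a) {
        const int va = g[(R_xlen_t)a * n + j];
        for (int b = a + 1; b < m; ++b) {
          if (va != g[(R_xlen_t)b * n + j]) {
            --dist[a * m + b];
            --dist[b * m + a];
          }
        }
      }
    }
    std::vector<int> next_alive;
    next_alive.reserve(na - n_remove);
    for (int q = 0; q < na; ++q)
      if (alive[alive_idx[q]]) next_alive.push_back(alive_idx[q]);
    alive_idx.swap(next_alive);
  }
  return List::create(_["ties"] = ties, _["participation"] = part);
}

// SURF-style update: every non-target sample strictly within `threshold`
// is a neighbour; hit and miss sides are normalised by their own counts so
// each sample contributes at most 1/M to any weight.
// [[Rcpp::export(name = ".surf_core_cpp")]]
NumericVector surf_core_cpp(const IntegerMatrix& gt, const IntegerMatrix& dist,
                            const IntegerVector& labels, double threshold) {
  const int n = gt.nrow(), m = gt.ncol();
  std::vector<double> w(n, 0.0);
  std::vector<int> hits, misses;
  const int* g = INTEGER(gt);
  const int* d = INTEGER(dist);
  for (int i = 0; i < m; ++i) {
    hits.clear(); misses.clear();
    const int* di = d + (R_xlen_t)i * m;
    for (int b = 0; b < m; ++b) {
      if (b == i || di[b] >= threshold) continue;
      if (labels[b] == labels[i]) hits.push_back(b);
      else misses.push_back(b);
    }
    const int* gi = g + (R_xlen_t)i * n;
    if (!hits.empty()) {
      const double z = 1.0 / ((double)m * (double)hits.size());
      for (size_t k = 0; k < hits.size(); ++k) {
        const int* gh = g + (R_xlen_t)hits[k] * n;
        for (int j = 0; j < n; ++j) if (gi[j] != gh[j]) w[j] -= z;
      }
    }
    if (!misses.empty()) {
      const double z = 1.0 / ((double)m * (double)misses.size());
      for (size_t k = 0; k < misses.size(); ++k) {
        const int* gm = g + (R_xlen_t)misses[k] * n;
        for (int j = 0; j < n; ++j) if (gi[j] != gm[j]) w[j] += z;
      }
    }
  }
  return NumericVector(w.begin(), w.end());
}
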