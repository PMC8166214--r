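#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact K-th nearest-neighbor distances via a uniform bucket grid with
// expanding Chebyshev shells. Falls back to brute force for small
// reference sets. Deterministic: only distances are compared.
// [[Rcpp::export(name = ".cpp_kth_nn_dist")]]
NumericVector cpp_kth_nn_dist(NumericMatrix query, NumericMatrix ref, int K) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (K > nr) stop("K exceeds number of reference points");
  NumericVector out(nq);

  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }

  std::vector<double> best(K);
  if (nr <= 64) { // brute force
    for (int i = 0; i < nq; ++i) {
      const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
      int filled = 0;
      for (int j = 0; j < nr; ++j) {
        double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (filled < K) {
          best[filled++] = d2;
          if (filled == K) std::make_heap(best.begin(), best.end());
        } else if (d2 < best[0]) {
          std::pop_heap(best.begin(), best.end());
          best[K - 1] = d2;
          std::push_heap(best.begin(), best.end());
        }
      }
      out[i] = std::sqrt(best[0]);
    }
    return out;
  }

  // bucket grid sized so buckets hold a handful of points
  double lo[3] = {rx[0], ry[0], rz[0]}, hi[3] = {rx[0], ry[0], rz[0]};
  for (int j = 1; j < nr; ++j) {
    lo[0] = std::min(lo[0], rx[j]); hi[0] = std::max(hi[0], rx[j]);
    lo[1] = std::min(lo[1], ry[j]); hi[1] = std::max(hi[1], ry[j]);
    lo[2] = std::min(lo[2], rz[j]); hi[2] = std::max(hi[2], rz[j]);
  }
  double vol = std::max(hi[0] - lo[0], 1e-9) * std::max(hi[1] - lo[1], 1e-9) *
               std::max(hi[2] - lo[2], 1e-9);
  double h = std::cbrt(vol * std::max(K, 4) / (double)nr);
  h = std::max(h, 1e-6);
  int nb[3];
  for (int d = 0; d < 3; ++d) {
    nb[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
    nb[d] = std::min(nb[d], 256);
  }
  // counting sort of reference points into buckets
  const long nbuck = (long)nb[0] * nb[1] * nb[2];
  std::vector<int> bucket_of(nr);
  std::vector<int> counts(nbuck + 1, 0);
  for (int j = 0; j < nr; ++j) {
    int bx = std::min((int)((rx[j] - lo[0]) / h), nb[0] - 1);
    int by = std::min((int)((ry[j] - lo[1]) / h), nb[1] - 1);
    int bz = std::min((int)((rz[j] - lo[2]) / h), nb[2] - 1);
    int b = bx + nb[0] * (by + nb[1] * bz);
    bucket_of[j] = b;
    counts[b + 1]++;
  }
  for (long b = 0; b < nbuck; ++b) counts[b + 1] += counts[b];
  std::vector<int> order(nr);
  {
    std::vector<int> cursor(counts.begin(), counts.end() - 1);
    for (int j = 0; j < nr; ++j) order[cursor[bucket_of[j]]++] = j;
  }

  const int max_ring = std::max(nb[0], std::max(nb[1], nb[2]));
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int cx = std::min(std::max((int)((qx - lo[0]) / h), 0), nb[0] - 1);
    int cy = std::min(std::max((int)((qy - lo[1]) / h), 0), nb[1] - 1);
    int cz = std::min(std::max((int)((qz - lo[2]) / h), 0), nb[2] - 1);
    int filled = 0;
    for (int ring = 0; ring <= max_ring; ++ring) {
      // shells beyond `ring` only contain points at distance >= (ring-1)*h
      if (filled == K) {
        double bound = (ring - 1.0) * h;
        if (bound > 0 && best[0] <= bound * bound) break;
      }
      for (int bz = cz - ring; bz <= cz + ring; ++bz) {
        if (bz < 0 || bz >= nb[2]) continue;
        for (int by = cy - ring; by <= cy + ring; ++by) {
          if (by < 0 || by >= nb[1]) continue;
          for (int bx = cx - ring; bx <= cx + ring; ++bx) {
            if (bx < 0 || bx >= nb[0]) continue;
            int cheb = std::max(std::abs(bx - cx),
                                std::max(std::abs(by - cy), std::abs(bz - cz)));
            if (cheb != ring) continue;
            int b = bx + nb[0] * (by + nb[1] * bz);
            for (int t = counts[b]; t < counts[b + 1]; ++t) {
              int j = order[t];
              double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (filled < K) {
                best[filled++] = d2;
                if (filled == K) std::make_heap(best.begin(), best.end());
              } else if (d2 < best[0]) {
                std::pop_heap(best.begin(), best.end());
                best[K - 1] = d2;
                std::push_heap(best.begin(), best.end());
              }
            }
          }
        }
      }
    }
    out[i] = std::sqrt(best[0]);
  }
  return out;
}

// Nearest reference point per query: returns distance and the reference
// label (ties broken toward the smallest label so results are
// permutation-invariant in the input ordering).
// [[Rcpp::export(name = ".cpp_nearest_labeled")]]
List cpp_nearest_labeled(NumericMatrix query, NumericMatrix ref,
                         IntegerVector labels) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector dist(nq);
  IntegerVector lab(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    double bd = R_PosInf;
    int bl = NA_INTEGER;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bd - 1e-12 || (std::abs(d2 - bd) <= 1e-12 && labels[j] < bl)) {
        bd = d2;
        bl = labels[j];
      }
    }
    dist[i] = std::sqrt(bd);
    lab[i] = bl;
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}

// For Q (point, group) pairs, the minimum distance from the point to any
// reference point of that group. Reference points are pre-sorted by group;
// start/end are 1-based inclusive offsets per group.
// [[Rcpp::export(name = ".cpp_pair_min_dist")]]
NumericVector cpp_pair_min_dist(NumericMatrix pts, IntegerVector pair_pt,
                                IntegerVector pair_group, NumericMatrix ref,
                                IntegerVector start, IntegerVector end) {
  const int q = pair_pt.size();
  NumericVector out(q);
  for (int i = 0; i < q; ++i) {
    const int p = pair_pt[i] - 1;
    const int g = pair_group[i] - 1;
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double bd = R_PosInf;
    for (int j = start[g] - 1; j < end[g]; ++j) {
      double dx = ref(j, 0) - px, dy = ref(j, 1) - py, dz = ref(j, 2) - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bd) bd = d2;
    }
    out[i] = std::sqrt(bd);
  }
  return out;
}
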