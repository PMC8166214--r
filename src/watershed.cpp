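#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Marker-based compact watershed (Meyer's priority flood with an optional
// compactness term and an optional one-voxel watershed line), 6-connectivity
// in 3D. Priority of a voxel claimed by region L is
//   elevation + compactness * squared physical distance to L's seed centroid.
// Deterministic: ties broken by insertion order.
// Output labels: 0 = unlabeled (outside mask or watershed line).
// [[Rcpp::export(name = ".cpp_compact_watershed")]]
IntegerVector cpp_compact_watershed(IntegerVector dims, NumericVector elevation,
                                    IntegerVector seeds, LogicalVector mask,
                                    double compactness, NumericVector spacing,
                                    bool line) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<char> done(n, 0); // 1 = labeled or line

  // seed centroids in physical coordinates (voxel centers)
  int maxlab = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (seeds[i] > maxlab) maxlab = seeds[i];
  std::vector<double> cx(maxlab + 1, 0), cy(maxlab + 1, 0), cz(maxlab + 1, 0);
  std::vector<double> cn(maxlab + 1, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        int s = seeds[i];
        if (s > 0) {
          cx[s] += (x + 0.5) * spacing[0];
          cy[s] += (y + 0.5) * spacing[1];
          cz[s] += (z + 0.5) * spacing[2];
          cn[s] += 1;
        }
      }
  for (int s = 1; s <= maxlab; ++s)
    if (cn[s] > 0) { cx[s] /= cn[s]; cy[s] /= cn[s]; cz[s] /= cn[s]; }

  typedef std::tuple<double, unsigned long long, R_xlen_t, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  unsigned long long counter = 0;

  const int dx6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, -1, 1};

  // seeds are fixed labels
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0) { out[i] = seeds[i]; done[i] = 1; }

  // push masked neighbors of seeds
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        if (!done[i]) continue;
        int lab = out[i];
        for (int k = 0; k < 6; ++k) {
          int xx = x + dx6[k], yy = y + dy6[k], zz = z + dz6[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t j = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
          if (done[j] || !mask[j]) continue;
          double px = (xx + 0.5) * spacing[0] - cx[lab];
          double py = (yy + 0.5) * spacing[1] - cy[lab];
          double pz = (zz + 0.5) * spacing[2] - cz[lab];
          double pr = elevation[j] +
                      compactness * (px * px + py * py + pz * pz);
          pq.push(QE(pr, counter++, j, lab));
        }
      }

  while (!pq.empty()) {
    QE e = pq.top();
    pq.pop();
    R_xlen_t i = std::get<2>(e);
    if (done[i]) continue;
    int lab = std::get<3>(e);
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;

    if (line) {
      // Meyer: a voxel touched by two established regions becomes the line
      bool conflict = false;
      for (int k = 0; k < 6 && !conflict; ++k) {
        int xx = x + dx6[k], yy = y + dy6[k], zz = z + dz6[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
        if (done[j] && out[j] > 0 && out[j] != lab) conflict = true;
      }
      if (conflict) {
        done[i] = 1; // line voxel, stays 0
        continue;
      }
    }

    out[i] = lab;
    done[i] = 1;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx6[k], yy = y + dy6[k], zz = z + dz6[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
      if (done[j] || !mask[j]) continue;
      double px = (xx + 0.5) * spacing[0] - cx[lab];
      double py = (yy + 0.5) * spacing[1] - cy[lab];
      double pz = (zz + 0.5) * spacing[2] - cz[lab];
      double pr = elevation[j] + compactness * (px * px + py * py + pz * pz);
      pq.push(QE(pr, counter++, j, lab));
    }
  }
  out.attr("dim") = dims;
  return out;
}
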