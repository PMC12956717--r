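#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared-distance transform with
// feature (nearest-site) tracking.  Sites are the zero-distance voxels;
// every voxel receives the distance (in mm, via anisotropic axis weights)
// to the nearest site voxel centre and that site's linear index.

static const double BIG = 1e20;

// 1D pass over one line: f = current squared distances, feat = current
// nearest-site indices; w = physical step along this axis.
static void dt1d(std::vector<double>& f, std::vector<int>& feat, double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> fout(n);
  std::vector<int> featout(n);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double d = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
    fout[q] = d;
    featout[q] = feat[v[k]];
  }
  f = fout;
  feat = featout;
}

// [[Rcpp::export]]
List edt_feature_cpp(LogicalVector sites, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sites.size() != n) stop("sites length does not match dim");
  bool any_site = false;
  std::vector<double> d2(n);
  std::vector<int> feat(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (sites[i]) { d2[i] = 0.0; feat[i] = (int)i; any_site = true; }
    else { d2[i] = BIG; feat[i] = -1; }
  }
  if (!any_site) stop("no site voxels: distance transform undefined");

  std::vector<double> line;
  std::vector<int> lfeat;

  // axis x (fastest varying)
  line.resize(nx); lfeat.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) { line[x] = d2[base + x]; lfeat[x] = feat[base + x]; }
      dt1d(line, lfeat, spacing[0]);
      for (int x = 0; x < nx; x++) { d2[base + x] = line[x]; feat[base + x] = lfeat[x]; }
    }
  // axis y
  line.resize(ny); lfeat.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) { line[y] = d2[base + (R_xlen_t)y * nx]; lfeat[y] = feat[base + (R_xlen_t)y * nx]; }
      dt1d(line, lfeat, spacing[1]);
      for (int y = 0; y < ny; y++) { d2[base + (R_xlen_t)y * nx] = line[y]; feat[base + (R_xlen_t)y * nx] = lfeat[y]; }
    }
  // axis z
  line.resize(nz); lfeat.resize(nz);
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) { line[z] = d2[base + (R_xlen_t)z * stz]; lfeat[z] = feat[base + (R_xlen_t)z * stz]; }
      dt1d(line, lfeat, spacing[2]);
      for (int z = 0; z < nz; z++) { d2[base + (R_xlen_t)z * stz] = line[z]; feat[base + (R_xlen_t)z * stz] = lfeat[z]; }
    }

  NumericVector dist(n);
  IntegerVector nearest(n);
  for (R_xlen_t i = 0; i < n; i++) {
    dist[i] = std::sqrt(d2[i]);
    nearest[i] = feat[i] + 1;  // 1-based for R
  }
  dist.attr("dim") = dim;
  nearest.attr("dim") = dim;
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Ridge test: TRUE where value >= max over the 26-neighbourhood (ties keep
// plateaus).  Used to pick medial-axis voxels off the distance transform.
// [[Rcpp::export]]
LogicalVector local_ridge_cpp(NumericVector val, IntegerVector dim, double tol) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = (R_xlen_t)z * stz + (R_xlen_t)y * nx + x;
        double v = val[i];
        if (v <= 0) { out[i] = false; continue; }
        bool ridge = true;
        for (int dz = -1; dz <= 1 && ridge; dz++)
          for (int dy = -1; dy <= 1 && ridge; dy++)
            for (int dx = -1; dx <= 1 && ridge; dx++) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
              double u = val[(R_xlen_t)zz * stz + (R_xlen_t)yy * nx + xx];
              if (u > v + tol) ridge = false;
            }
        out[i] = ridge;
      }
  out.attr("dim") = dim;
  return out;
}

// 2D connected-component labelling (4- or 8-connectivity), BFS flood fill.
// [[Rcpp::export]]
IntegerMatrix label2d_cpp(LogicalMatrix m, bool eight) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  const int dx4[] = {1,-1,0,0}, dy4[] = {0,0,1,-1};
  const int dx8[] = {1,-1,0,0,1,1,-1,-1}, dy8[] = {0,0,1,-1,1,-1,1,-1};
  const int* dx = eight ? dx8 : dx4;
  const int* dy = eight ? dy8 : dy4;
  const int nd = eight ? 8 : 4;
  for (int c = 0; c < nc; c++)
    for (int r = 0; r < nr; r++) {
      if (!m(r, c) || lab(r, c)) continue;
      next++;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int k = 0; k < nd; k++) {
          int rr = p.first + dx[k], cc = p.second + dy[k];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (m(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}
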