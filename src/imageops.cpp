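// 3D voxel-grid primitives used across the pipeline: connected-component
// labeling under 6/18/26-connectivity, binary morphology with a physical
// (mm) ball structuring element, seeded region growing, a front-propagation
// (Dijkstra / fast-marching style) variant, and separable Gaussian blur.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

struct Off { int dx, dy, dz; };

static std::vector<Off> neighborhood(int connectivity) {
  std::vector<Off> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

#define IDX(x, y, z) ((size_t)(x) + nx * ((size_t)(y) + (size_t)ny * (z)))

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Off> offs = neighborhood(connectivity);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<size_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = IDX(x, y, z);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const size_t c = stack.back(); stack.pop_back();
          const int cz = c / ((size_t)nx * ny);
          const size_t rem = c - (size_t)cz * nx * ny;
          const int cy = rem / nx, cx = rem % nx;
          for (const Off& o : offs) {
            const int px = cx + o.dx, py = cy + o.dy, pz = cz + o.dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
            const size_t j = IDX(px, py, pz);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

static std::vector<Off> ball_offsets(NumericVector spacing, double radius_mm) {
  std::vector<Off> offs;
  const int rx = (int)std::floor(radius_mm / spacing[0]);
  const int ry = (int)std::floor(radius_mm / spacing[1]);
  const int rz = (int)std::floor(radius_mm / spacing[2]);
  const double r2 = radius_mm * radius_mm;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        const double d2 = dx * spacing[0] * dx * spacing[0] +
                          dy * spacing[1] * dy * spacing[1] +
                          dz * spacing[2] * dz * spacing[2];
        if (d2 <= r2) offs.push_back({dx, dy, dz});
      }
  return offs;
}

// [[Rcpp::export]]
LogicalVector cpp_morph_ball(LogicalVector mask, IntegerVector dims,
                             NumericVector spacing, double radius_mm,
                             bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Off> offs = ball_offsets(spacing, radius_mm);
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = IDX(x, y, z);
        if (dilate) {
          bool hit = false;
          for (const Off& o : offs) {
            const int px = x + o.dx, py = y + o.dy, pz = z + o.dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
            if (mask[IDX(px, py, pz)]) { hit = true; break; }
          }
          out[i] = hit;
        } else {
          if (!mask[i]) { out[i] = false; continue; }
          bool all = true;
          for (const Off& o : offs) {
            const int px = x + o.dx, py = y + o.dy, pz = z + o.dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) { all = false; break; }
            if (!mask[IDX(px, py, pz)]) { all = false; break; }
          }
          out[i] = all;
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, LogicalVector seeds,
                              LogicalVector allowed, double threshold,
                              IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Off> offs = neighborhood(connectivity);
  LogicalVector out(img.size(), FALSE);
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)img.size(); ++i)
    if (seeds[i] && allowed[i] && img[i] >= threshold) { out[i] = true; stack.push_back(i); }
  while (!stack.empty()) {
    const size_t c = stack.back(); stack.pop_back();
    const int cz = c / ((size_t)nx * ny);
    const size_t rem = c - (size_t)cz * nx * ny;
    const int cy = rem / nx, cx = rem % nx;
    for (const Off& o : offs) {
      const int px = cx + o.dx, py = cy + o.dy, pz = cz + o.dz;
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
      const size_t j = IDX(px, py, pz);
      if (!out[j] && allowed[j] && img[j] >= threshold) { out[j] = true; stack.push_back(j); }
    }
  }
  return out;
}

// Front propagation from the seeds with local speed proportional to uptake:
// arrival times via Dijkstra on the voxel graph with edge cost
// dist(mm) / mean(speed at both ends). Voxels reached within the constraint
// region and lying at or above the inclusion threshold are kept.
// [[Rcpp::export]]
LogicalVector cpp_front_grow(NumericVector img, LogicalVector seeds,
                             LogicalVector allowed, double threshold,
                             IntegerVector dims, NumericVector spacing,
                             int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Off> offs = neighborhood(connectivity);
  std::vector<double> dist(img.size(), R_PosInf);
  typedef std::pair<double, size_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (size_t i = 0; i < (size_t)img.size(); ++i)
    if (seeds[i] && allowed[i] && img[i] >= threshold) { dist[i] = 0; pq.push({0.0, i}); }
  while (!pq.empty()) {
    const Node nd = pq.top(); pq.pop();
    const size_t c = nd.second;
    if (nd.first > dist[c]) continue;
    const int cz = c / ((size_t)nx * ny);
    const size_t rem = c - (size_t)cz * nx * ny;
    const int cy = rem / nx, cx = rem % nx;
    for (const Off& o : offs) {
      const int px = cx + o.dx, py = cy + o.dy, pz = cz + o.dz;
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
      const size_t j = IDX(px, py, pz);
      if (!allowed[j] || img[j] < threshold) continue;
      const double step = std::sqrt(o.dx * spacing[0] * o.dx * spacing[0] +
                                    o.dy * spacing[1] * o.dy * spacing[1] +
                                    o.dz * spacing[2] * o.dz * spacing[2]);
      const double speed = std::max(0.5 * (img[c] + img[j]), 1e-6);
      const double nd2 = dist[c] + step / speed;
      if (nd2 < dist[j]) { dist[j] = nd2; pq.push({nd2, j}); }
    }
  }
  LogicalVector out(img.size(), FALSE);
  for (size_t i = 0; i < (size_t)img.size(); ++i) out[i] = R_FINITE(dist[i]);
  return out;
}

// separable Gaussian along each axis; sigma in voxel units, radius 3 sigma
static void blur_axis(std::vector<double>& v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) { k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + rad]; }
  for (double& w : k) w /= s;
  const size_t nxy = (size_t)nx * ny;
  std::vector<double> tmp(v.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t i = IDX(x, y, z);
        double acc = 0;
        for (int t = -rad; t <= rad; ++t) {
          int px = x, py = y, pz = z;
          if (axis == 0) px = std::min(std::max(x + t, 0), nx - 1);
          else if (axis == 1) py = std::min(std::max(y + t, 0), ny - 1);
          else pz = std::min(std::max(z + t, 0), nz - 1);
          acc += k[t + rad] * v[IDX(px, py, pz)];
        }
        tmp[i] = acc;
      }
  v.swap(tmp);
  (void)nxy;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector img, IntegerVector dims,
                                  NumericVector sigma_vox) {
  std::vector<double> v(img.begin(), img.end());
  blur_axis(v, dims[0], dims[1], dims[2], 0, sigma_vox[0]);
  blur_axis(v, dims[0], dims[1], dims[2], 1, sigma_vox[1]);
  blur_axis(v, dims[0], dims[1], dims[2], 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// In-plane affine augmentation of a slice and its label map: rotation about
// the slice center, isotropic scale, translation (voxels), optional
// left-right flip. Bilinear sampling for the image, nearest for labels.
// [[Rcpp::export]]
List cpp_affine_slice(NumericMatrix img, IntegerMatrix lab, double angle_deg,
                      double tx, double ty, double scale, bool flip) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix oimg(H, W);
  IntegerMatrix olab(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);
  const double cx = (H - 1) / 2.0, cy = (W - 1) / 2.0;
  // inverse map: out (i,j) -> source (si,sj)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double u = i - cx - tx, v = j - cy - ty;
      double su = (ca * u + sa * v) / scale;
      double sv = (-sa * u + ca * v) / scale;
      double si = su + cx, sj = sv + cy;
      if (flip) si = (H - 1) - si;
      // nearest for labels
      const int ni = (int)std::lround(si), nj = (int)std::lround(sj);
      olab(i, j) = (ni >= 0 && ni < H && nj >= 0 && nj < W) ? lab(ni, nj) : 0;
      // bilinear for image (zero padding outside)
      const int f0 = (int)std::floor(si), g0 = (int)std::floor(sj);
      const double wi = si - f0, wj = sj - g0;
      double acc = 0;
      for (int di = 0; di <= 1; ++di)
        for (int dj = 0; dj <= 1; ++dj) {
          const int pi = f0 + di, pj = g0 + dj;
          if (pi < 0 || pi >= H || pj < 0 || pj >= W) continue;
          acc += img(pi, pj) * (di ? wi : 1 - wi) * (dj ? wj : 1 - wj);
        }
      oimg(i, j) = acc;
    }
  }
  return List::create(_["image"] = oimg, _["labels"] = olab);
}
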