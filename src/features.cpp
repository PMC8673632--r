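#include <Rcpp.h>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major, so z is the
// fastest-varying axis: offset(z,y,x) = z + nz*(y + ny*x).  All coordinates
// here are 0-based.  Border handling is edge replication (clamped indexing)
// so every voxel has a full-size neighbourhood.

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Linear binning of v into k bins over [lo, hi]; out-of-range values are
// clamped into the end bins.
static inline int bin_of(double v, double lo, double hi, int k) {
  if (hi <= lo) return 0;
  int b = (int)std::floor((v - lo) / (hi - lo) * k);
  if (b < 0) b = 0;
  if (b >= k) b = k - 1;
  return b;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hist_at(NumericVector vol, IntegerVector dim,
                          IntegerMatrix coords, int r,
                          double lo, double hi, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = coords.nrow();
  IntegerMatrix out(k, n);
  for (int i = 0; i < n; ++i) {
    const int z = coords(i, 0), y = coords(i, 1), x = coords(i, 2);
    for (int dx = -r; dx <= r; ++dx) {
      const int xx = clampi(x + dx, nx);
      for (int dy = -r; dy <= r; ++dy) {
        const int yy = clampi(y + dy, ny);
        const double *col = &vol[0] + (size_t)nz * (yy + (size_t)ny * xx);
        for (int dz = -r; dz <= r; ++dz) {
          const int zz = clampi(z + dz, nz);
          out(bin_of(col[zz], lo, hi, k), i)++;
        }
      }
    }
  }
  return out;
}

// Incremental sliding-window histograms for every voxel with z in [z0, z1).
// Per (y, x) column the first histogram is computed independently; each
// subsequent one subtracts the departing xy-plane slice of the cube at
// z - 1 - r and adds the arriving one at z + r, an O(r^2) update.
// Output column order matches an array of dim (z1-z0, ny, nx).
// [[Rcpp::export]]
IntegerMatrix cpp_hist_block(NumericVector vol, IntegerVector dim,
                             int z0, int z1, int r,
                             double lo, double hi, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int nzs = z1 - z0;
  IntegerMatrix out(k, (size_t)nzs * ny * nx);
  std::vector<int> h(k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      std::fill(h.begin(), h.end(), 0);
      // full cube at the first centre
      for (int dx = -r; dx <= r; ++dx) {
        const int xx = clampi(x + dx, nx);
        for (int dy = -r; dy <= r; ++dy) {
          const int yy = clampi(y + dy, ny);
          const double *col = &vol[0] + (size_t)nz * (yy + (size_t)ny * xx);
          for (int dz = -r; dz <= r; ++dz)
            h[bin_of(col[clampi(z0 + dz, nz)], lo, hi, k)]++;
        }
      }
      size_t vi = (size_t)nzs * (y + (size_t)ny * x);
      for (int b = 0; b < k; ++b) out(b, vi) = h[b];
      for (int z = z0 + 1; z < z1; ++z) {
        const int zout = clampi(z - 1 - r, nz), zin = clampi(z + r, nz);
        for (int dx = -r; dx <= r; ++dx) {
          const int xx = clampi(x + dx, nx);
          for (int dy = -r; dy <= r; ++dy) {
            const int yy = clampi(y + dy, ny);
            const double *col = &vol[0] + (size_t)nz * (yy + (size_t)ny * xx);
            h[bin_of(col[zout], lo, hi, k)]--;
            h[bin_of(col[zin], lo, hi, k)]++;
          }
        }
        const size_t vj = vi + (z - z0);
        for (int b = 0; b < k; ++b) out(b, vj) = h[b];
      }
    }
  }
  return out;
}

// Uniform rotation-invariant LBP code of one 3x3 patch given as the centre
// value and the 8 ring neighbours in circular order.  Threshold is
// neighbour >= centre -> bit 1.  <= 2 circular transitions -> code = number
// of set bits (0..8); otherwise 9.
static inline int lbp_code_ring(const double *ring, double centre) {
  int bits[8], ones = 0, trans = 0;
  for (int i = 0; i < 8; ++i) {
    bits[i] = (ring[i] >= centre) ? 1 : 0;
    ones += bits[i];
  }
  for (int i = 0; i < 8; ++i) trans += (bits[i] != bits[(i + 1) % 8]);
  return (trans <= 2) ? ones : 9;
}

// Ring offsets: start at (-1, 0) in (row, col) = (a, b) patch coordinates,
// proceeding clockwise.
static const int RA[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RB[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Per-voxel LBP codes over a whole volume, on the plane selected:
// plane 0 = xy (ring varies in y, x), 1 = yz (varies z, y), 2 = xz
// (varies z, x).  Edge replication at borders.
// [[Rcpp::export]]
IntegerVector cpp_lbp_codes(NumericVector vol, IntegerVector dim, int plane) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out((size_t)nz * ny * nx);
  // in-plane axes (a, b) as axis ids: 0=z, 1=y, 2=x
  int axa, axb;
  if (plane == 0)      { axa = 1; axb = 2; }
  else if (plane == 1) { axa = 0; axb = 1; }
  else                 { axa = 0; axb = 2; }
  const int nlen[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  double ring[8];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int c[3] = {z, y, x};
        const size_t off0 = z + (size_t)nz * (y + (size_t)ny * x);
        const double centre = vol[off0];
        for (int i = 0; i < 8; ++i) {
          int p[3] = {c[0], c[1], c[2]};
          p[axa] = clampi(c[axa] + RA[i], nlen[axa]);
          p[axb] = clampi(c[axb] + RB[i], nlen[axb]);
          ring[i] = vol[p[0] * stride[0] + p[1] * stride[1] + p[2] * stride[2]];
        }
        out[off0] = lbp_code_ring(ring, centre);
      }
  return out;
}

// Histogram (10 bins) of LBP codes in the (2r+1)^2 in-plane neighbourhood of
// each requested coordinate; naive per-coordinate count (the oracle path).
// [[Rcpp::export]]
IntegerMatrix cpp_plane_hist_at(IntegerVector codes, IntegerVector dim,
                                IntegerMatrix coords, int plane, int r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = coords.nrow();
  int axa, axb;
  if (plane == 0)      { axa = 1; axb = 2; }
  else if (plane == 1) { axa = 0; axb = 1; }
  else                 { axa = 0; axb = 2; }
  const int nlen[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  IntegerMatrix out(10, n);
  for (int i = 0; i < n; ++i) {
    int c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    for (int da = -r; da <= r; ++da)
      for (int db = -r; db <= r; ++db) {
        int p[3] = {c[0], c[1], c[2]};
        p[axa] = clampi(c[axa] + da, nlen[axa]);
        p[axb] = clampi(c[axb] + db, nlen[axb]);
        out(codes[p[0] * stride[0] + p[1] * stride[1] + p[2] * stride[2]], i)++;
      }
  }
  return out;
}

// Windowed LBP-code histograms for every voxel with z in [z0, z1),
// incremental along the first in-plane axis (subtract one line of the
// square, add one line: O(r) per step).  Output column order matches an
// array of dim (z1-z0, ny, nx).
// [[Rcpp::export]]
IntegerMatrix cpp_plane_hist_block(IntegerVector codes, IntegerVector dim,
                                   int z0, int z1, int plane, int r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int nzs = z1 - z0;
  int axa, axb;
  if (plane == 0)      { axa = 1; axb = 2; }
  else if (plane == 1) { axa = 0; axb = 1; }
  else                 { axa = 0; axb = 2; }
  const int nlen[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  IntegerMatrix out(10, (size_t)nzs * ny * nx);
  int h[10];
  // iterate with axa innermost so the window slides along axa
  // outer axes: the two axes other than axa, restricted to the slab in z
  const int lo0 = (axa == 0) ? z0 : 0;
  const int hi0 = (axa == 0) ? z1 : nlen[axa];
  // identify outer axes o1, o2
  int o1 = -1, o2 = -1;
  for (int ax = 0; ax < 3; ++ax) if (ax != axa) { if (o1 < 0) o1 = ax; else o2 = ax; }
  const int lo1 = (o1 == 0) ? z0 : 0, hi1 = (o1 == 0) ? z1 : nlen[o1];
  const int lo2 = (o2 == 0) ? z0 : 0, hi2 = (o2 == 0) ? z1 : nlen[o2];
  for (int i2 = lo2; i2 < hi2; ++i2)
    for (int i1 = lo1; i1 < hi1; ++i1) {
      for (int b = 0; b < 10; ++b) h[b] = 0;
      int c[3];
      c[o1] = i1; c[o2] = i2; c[axa] = lo0;
      // full window at the first centre along axa
      for (int da = -r; da <= r; ++da)
        for (int db = -r; db <= r; ++db) {
          int p[3] = {c[0], c[1], c[2]};
          p[axa] = clampi(c[axa] + da, nlen[axa]);
          p[axb] = clampi(c[axb] + db, nlen[axb]);
          h[codes[p[0] * stride[0] + p[1] * stride[1] + p[2] * stride[2]]]++;
        }
      for (int ia = lo0; ia < hi0; ++ia) {
        c[axa] = ia;
        if (ia > lo0) {
          const int aout = clampi(ia - 1 - r, nlen[axa]);
          const int ain = clampi(ia + r, nlen[axa]);
          for (int db = -r; db <= r; ++db) {
            int p[3] = {c[0], c[1], c[2]};
            p[axb] = clampi(c[axb] + db, nlen[axb]);
            p[axa] = aout;
            h[codes[p[0] * stride[0] + p[1] * stride[1] + p[2] * stride[2]]]--;
            p[axa] = ain;
            h[codes[p[0] * stride[0] + p[1] * stride[1] + p[2] * stride[2]]]++;
          }
        }
        const size_t vi = (size_t)(c[0] - z0) +
          (size_t)nzs * (c[1] + (size_t)ny * c[2]);
        for (int b = 0; b < 10; ++b) out(b, vi) = h[b];
      }
    }
  return out;
}

// Separable convolution along one axis (0=z, 1=y, 2=x) with a normalised
// kernel, reflect (edge-repeating) padding.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                int axis, NumericVector kernel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int nlen[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  const int kr = (kernel.size() - 1) / 2;
  const int n = nlen[axis];
  NumericVector out((size_t)nz * ny * nx);
  out.attr("dim") = dim;
  int o1 = -1, o2 = -1;
  for (int ax = 0; ax < 3; ++ax) if (ax != axis) { if (o1 < 0) o1 = ax; else o2 = ax; }
  for (int i2 = 0; i2 < nlen[o2]; ++i2)
    for (int i1 = 0; i1 < nlen[o1]; ++i1) {
      const size_t base = (size_t)i1 * stride[o1] + (size_t)i2 * stride[o2];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int dk = -kr; dk <= kr; ++dk) {
          int j = i + dk;
          while (j < 0 || j >= n) {            // reflect with edge repeat
            if (j < 0) j = -j - 1;
            if (j >= n) j = 2 * n - 1 - j;
          }
          acc += kernel[dk + kr] * vol[base + (size_t)j * stride[axis]];
        }
        out[base + (size_t)i * stride[axis]] = acc;
      }
    }
  return out;
}
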